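# larkin

Release-kinetics modelling and long-term exposure projection for
long-acting drug implants, built around the worked case of subcutaneous
levonorgestrel (LNG) devices (150 mg two-rod implants worn for up to five
years).

Contraceptive implants release drug over years, and the data available to
characterize that release are sparse and indirect: residual drug assayed in
devices explanted at a handful of time points, and a few release rates
quoted on the product label (0.1 mg/day at month 1, 0.04 mg/day at 12
months, 0.03 mg/day from 24 months). `larkin` turns such data into a
defensible long-term exposure projection in four steps:

1. **Release models.** Ten closed-form cumulative-release families
   Q(t) with exact analytic rates dQ/dt: zero-order, first-order
   (`Q = Qmax(1 − e^{−k1 t})`), second-order (solution of
   `dQ/dt = k2 (Qmax − Q)²`), Higuchi (`kH √t`), Korsmeyer–Peppas
   (`kkp tⁿ`), Hixson–Crowell (cube-root law, clamped at depletion),
   Weibull (`Qmax(1 − e^{−(kw t)^l})`), biexponential
   (`Dose − Qb1 e^{−kb1 t} − (Dose − Qb1) e^{−kb2 t}`), Peppas–Sahlin and
   Population Council, plus the exact special-case reductions between them.
2. **Estimation and selection.** Bounded nonlinear least squares jointly
   over cumulative-amount and release-rate observations, with Wald
   confidence intervals, delta-method prediction bands, and ranking by
   adjusted R².
3. **Input functions.** The exponential families convert into
   releasable-fraction-corrected implant input functions
   `L(t) = (1 − f)·Dose·e^{−k1 t}` (and its biexponential analogue), where
   `(1 − f)` — about 50% from end-of-trial residual-drug data — is the
   fraction of the load that is ever released.
4. **Exposure projection.** A reduced subcutaneous-depot + one-compartment
   disposition model driven by the input function projects plasma
   concentration (pg/mL) over five years, with exposure metrics (Cmax,
   AUC, Cavg), predicted/observed ratios, a 1.25×-error adequacy rule, and
   median-preserving lognormal inter-individual variability.

A seeded synthetic-data generator emulates the device-removal study design
end to end, so the whole pipeline is testable without clinical data.

## Worked example

Generate a noisy five-year device-removal dataset (13 sampling times, 5
implants per time, 2 mg assay noise), fit and rank release models, then
project plasma exposure:

```r
library(larkin)

implant <- lng_implant_150()            # 150 mg, 2 rods, (1 - f) = 0.5
cfg <- synthetic_config(
  family = "first_order", params = list(Qmax = 67.86, k1 = 9e-4),
  implant = implant, noise = list(additive_sd = 2), seed = 42
)
obs <- generate_ex_vivo(cfg)
fit <- fit_release_model(obs, "first_order")
fit
#> <release_fit> first_order on 13 observation(s)
#>   Qmax  66.3536  (95% CI 61.5004, 71.2068)
#>   k1    0.000946104  (95% CI 0.0008173, 0.00107491)
#>   SSE = 12.1652, R2 = 0.9972, adjusted R2 = 0.9966
```

The recovered asymptote (~66 mg, i.e. ~44% of the load) and rate constant
(~0.00095/day) bracket the generating truth; the intervals quantify how
well 13 sparse means pin them down. Competing families are ranked by
adjusted R², ties going to the smaller model:

```r
fits <- list(fit,
             fit_release_model(obs, "weibull"),
             fit_release_model(obs, "higuchi"))
compare_models(fits)
#> # A tibble: 3 × 7
#>    rank family_id   adjusted_r2    r2   sse n_params converged
#>   <int> <chr>             <dbl> <dbl> <dbl>    <int> <lgl>
#> 1     1 first_order       0.997 0.997  12.2        2 TRUE
#> 2     2 weibull           0.997 0.997  11.0        3 TRUE
#> 3     3 higuchi           0.952 0.956 188.         1 TRUE
```

The winning fit drives the plasma projection:

```r
prof <- simulate_concentration(implant, "first_order", fit$estimates,
                               disposition_params(), times = seq(0, 1825, by = 1))
exposure_metrics(prof)
#> # A tibble: 1 × 4
#>    cmax  tmax     auc  cavg
#>   <dbl> <dbl>   <dbl> <dbl>
#> 1  614.    13 539165.  295.
```

— an early peak of ~614 pg/mL two weeks after insertion, declining with
the release rate constant to give a five-year average around 300 pg/mL,
the concentration range reported for LNG implants. `autoplot()` methods
draw the fit with its prediction band, the concentration profile, and
population percentile bands from `simulate_population()`.

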