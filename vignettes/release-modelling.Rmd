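---
title: "Modelling implant release kinetics and projecting systemic exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling implant release kinetics and projecting systemic exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larkin)
```

## The problem

Subcutaneous contraceptive implants release levonorgestrel (LNG) over
three to five years. The release process itself is observed only
indirectly: a few dozen devices explanted at scattered times and assayed
for residual drug, and a handful of release rates quoted on the product
label at month marks. From these sparse observations one wants (i) a
parametric description of the cumulative release Q(t), (ii) an honest
statement of its uncertainty, and (iii) a projection of the plasma
concentrations the release profile implies, including between-subject
variability. `larkin` implements that chain.

## Release-model families

Ten families are implemented, each with a closed-form cumulative release
Q(t) in mg and its exact analytic rate in mg/day (`release_amount()`,
`release_rate()`). Three are exponential and approach an asymptote —
first-order, Weibull, biexponential; one is rational — second-order; six
are polynomial and unbounded — zero-order, Higuchi, Korsmeyer–Peppas,
Hixson–Crowell, Peppas–Sahlin, Population Council. The bounded/unbounded
distinction matters scientifically: a polynomial family can fit a
five-year window well yet eventually exceed the drug load, so it cannot
represent a device with a finite releasable reservoir. The ranking
operation treats all families alike; the physical argument for preferring
bounded families at multi-year horizons belongs to the analyst and is
documented here rather than hard-coded.

Two printed-form subtleties are resolved in the package's own way:

* **Second-order.** The closed form is implemented as the solution of
  `dQ/dt = k2 (Qmax − Q)²`, namely `Q = Qmax(1 − 1/(1 + Qmax k2 t))`. The
  alternative sign convention (denominator `1 − Qmax k2 t`) has a
  finite-time singularity and goes negative for positive rate constants,
  so it is not exposed at all.
* **Hixson–Crowell.** The cube-root law reaches complete depletion at
  `t = Qhc^{1/3}/khc` and re-grows unphysically past it; `larkin` clamps
  Q at `Qhc` from that time on and attaches a classed warning
  (`larkin_depletion_clamp`) so the clamp is visible, not silent.

Special-case reductions (`reduce_special_case()`) are performed only where
they are exact — Weibull `l = 1` to first-order, Korsmeyer–Peppas `n = 1`
to zero-order and `n = 0.5` to Higuchi, Peppas–Sahlin `m = 0.5` to
Population Council — with an exponent tolerance of 1e-12. Release-kinetics
texts sometimes label the Korsmeyer–Peppas exponent `n = 0.45` as the
Higuchi case (a thin-film geometry argument); since the package's Higuchi
family is exactly `kH √t`, reducing at 0.45 would change the curve, and
the reduction is therefore anchored at 0.5.

## The releasable fraction and the input function

Ex vivo residual-drug data show that only about half the 150 mg load is
ever released. This enters as the complement `f` in `implant_spec()`:
the releasable amount is `(1 − f)·Dose`, 75 mg at the default `f = 0.5`.
The exponential families then become implant input functions
(`remaining_releasable()`, `implant_input_rate()`):

* first-order: `L(t) = (1 − f)·Dose·e^{−k1 t}`
* biexponential: `L(t) = (1 − f)·(Qb1 e^{−kb1 t} + (Dose − Qb1) e^{−kb2 t})`

For the biexponential there is a genuine convention question: fits fix
`Dose` at the full 150 mg load, so applying `(1 − f)` afterwards corrects
a curve whose asymptote was already the full dose. The printed convention
(the `(1 − f)` prefactor multiplying both terms) is the default; a
`rescale_qb1` switch re-expresses the same correction by rescaling the
phase amounts while preserving the fitted split `Qb1 : (Dose − Qb1)`. The
two readings produce identical curves — both scale the whole profile by
`(1 − f)` — and the switch exists so the convention is explicit and
auditable rather than implicit.

## Estimation

`fit_release_model()` minimizes

```
SSE(θ) = Σ_amounts (q_i − Q(t_i; θ))² + w · Σ_rates (r_j − dQ/dt(t_j; θ))²
```

by bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`,
cost tolerance 1e-10, at most 500 iterations). Design choices an analyst
should know:

* **Joint amount + rate weighting.** Release amounts are tens of mg; label
  rates are hundredths of mg/day. With `rate_weight = "auto"` the weight is
  `(mean amount / mean rate)²`, which makes one rate residual contribute
  comparably to one amount residual after scale normalization. The resolved
  weight is echoed in the fit object; `rate_weight = 0` ignores rates, and
  an explicit number takes precedence.
* **Automatic starting values** are data-scaled and neutral: asymptote-like
  amounts start at half the load; day⁻¹ rate constants at `1/t_max`;
  exponents at 0.5; polynomial coefficients at the observed amount scale
  divided by the matching power of `t_max`. The biexponential is the one
  family where symmetric starts fail structurally — equal rate constants
  make the two phases indistinguishable and the Jacobian singular — so its
  starts are staggered a factor of ten on either side of `1/t_max`.
* **Bounds** keep day⁻¹ rate constants in `[1e-7, 1]`, amounts in
  `(0, dose]`, exponents in `[1e-3, 10]`.
* **Jacobians** are analytic where the registry carries closed-form
  parameter gradients (first-order, biexponential, zero-order, Higuchi,
  Population Council — the families that matter for the headline analysis)
  and finite-difference otherwise; the covariance at the optimum always
  uses the same residual Jacobian as the optimizer.
* **Uncertainty** is linearized: covariance `σ̂²(JᵀJ)⁻¹` with
  `σ̂² = SSE/(n − p)`, Wald intervals with t-quantiles
  (`parameter_cis()`), and delta-method prediction bands
  `Q̂ ± t·sqrt(σ̂² + gᵀCg)` (`prediction_band()`). Intervals for poorly
  identified parameters (the biexponential fast phase on sparse data) can
  span negative values; they are flagged (`spans_zero`), never truncated,
  because truncation would hide the identifiability problem.
* **R² convention.** The total sum of squares uses the amount
  observations only; rate observations contribute to the SSE as auxiliary
  calibration data but not to the SST. Adjusted R²
  (`1 − (1 − R²)(n − 1)/(n − p − 1)`) uses the full residual count `n`.
  This is stated prominently because mixed-type objectives admit several
  R² conventions and ranking depends on the choice.
* **Degenerate inputs.** Fewer residuals than `p + 1` is an explicit
  error; non-convergence is a flag on the result (with the optimizer's
  info code), not an exception; a singular curvature matrix yields
  undefined standard errors with a warning.

`compare_models()` ranks fits by adjusted R² descending, breaking exact
ties toward fewer parameters and ranking non-converged fits last. It also
accepts a plain table of reported adjusted R² values so a published
ordering can be reproduced without the underlying data.

## The plasma model

The full physiological treatment of implant pharmacokinetics resolves the
skin's interstitial space within a whole-body PBPK platform. `larkin`
deliberately reduces this to the smallest model that preserves the
quantities of interest at multi-year horizons: a subcutaneous depot fed by
the implant input rate, first-order absorption `ka` into one well-stirred
central compartment (volume `V`), and linear clearance `CL`:

```
dA_depot/dt   = r_in(t) − ka·A_depot
dA_central/dt = F·ka·A_depot − (CL/V)·A_central
```

Concentration is `A_central/V`, reported in pg/mL (internal amounts in
mg; 1 mg/L = 1e6 pg/mL — pg/mL is the physiologic scale for LNG, whose
implant concentrations sit in the low hundreds of pg/mL). The default
disposition (`ka` 0.6 day⁻¹, `CL` 114.29 L/day, `V` 150 L, `F` 1) is a
placeholder calibrated only so that a 0.03–0.04 mg/day input settles near
350 pg/mL (steady state `R·F/CL`); real applications must supply
literature values. Because release is by far the slowest process, the
terminal decline of concentration is governed by the release constant —
the implant, not the body, sets the long-term shape.

Integration uses `deSolve::lsoda` at `rtol = 1e-11`, `atol = 1e-13`, with
cumulative released, eliminated and bioavailability-lost amounts carried
as extra states so mass balance is auditable to sub-microgram residue
over five years (the test suite holds it to 1e-6 mg). States more
negative than 1 ng abort the run; smaller negative excursions are
clipped to zero.

`exposure_metrics()` uses the grid maximum for Cmax and the linear
trapezoid for AUC. `adequacy_check()` implements the acceptance rule used
for long-acting products — a prediction is adequate at an observation if
it falls within 1.25 times that observation's error — with a relative
floating-point guard of 1e-6 so a zero-width window (zero error, or
`factor = 0`) still accepts numerically identical values.

## Population variability

`simulate_population()` applies independent lognormal multiplicative
deviates to chosen parameters: subject value `= typical·exp(σ_log z)`,
`σ_log = sqrt(log(1 + CV²))`. The deviates are median-preserving — no
`−σ²/2` mean correction — so the population median tracks the
typical-value profile, which is the convention under which reported
typical values are interpreted as medians. No parameter correlations are
imposed (none are available to inform them). All draws flow from a single
integer seed through `withr::with_seed`, leaving the session RNG state
untouched; identical seeds give bitwise-identical percentile bands.

## The synthetic-data generator

`generate_ex_vivo()` emulates the device-removal design: at each of 13
default sampling times (insertion, quarterly through year one, then
semiannually to day 1825), `n = 5` implants are drawn as
`remaining = dose − Q_true(t) + noise`, truncated to the physical range
`[0, dose]`, and summarized as mean released amount, SE `= sd/√n`, and
`n` — the form in which such studies publish. Defaults (13 × 5 design,
additive SD 2 mg, chosen to produce error bars of a few mg like those in
published release figures) are documented assumptions, not estimates: the
real studies' designs are not tabulated anywhere. Truncation at the load
is real measurement physics — at `t = 0` roughly half the draws exceed
the load and are clipped, slightly biasing the first point — and a
warning fires when more than half the draws at a time point truncate.
`generate_label_rates()` evaluates the true rate at month marks 1/12/24
(30.44 days/month); `generate_plasma_observations()` adds proportional
error to a simulated profile and reports `error = CV·true conc`, the
scale on which the adequacy rule operates.

What the generator does **not** emulate: assay-level chemistry
(extraction efficiency, chromatographic error structure), between-device
manufacturing variability with serial correlation over time, subject
dropout, and the possibility that the true release mechanism is in none
of the ten families. Passing recovery tests therefore demonstrate that
the estimation machinery is correct and well-calibrated under the stated
design, not that any particular family is true of real devices.

## Problem sizes and verification scale

The test suite verifies, among others: exact closed-form examples against
quadrature and finite differences (relative tolerance 1e-6); the
second-order ODE residual below 1e-9; noise-free self-recovery for all
ten families (SSE < 1e-6 mg²; parameters within 0.1% for one- and
two-parameter polynomial/exponential families, 1% for multi-exponential
and exponent-bearing ones); Wald interval coverage over 500 noisy
replicates of the 13 × 5 design (expected within 4 percentage points of
95%); prediction-band coverage of new observations over 300 replicates;
five-year mass balance to 1e-6 mg; agreement with a brute-force Euler
integration (step 0.005 day) to 0.5%; and bitwise seed reproducibility.
Population checks use up to 1000 subjects on a one-year grid. These sizes
were chosen as the smallest designs at which the Monte-Carlo tolerances
above are meaningful.

## Known limitations

* The disposition model is a reduced surrogate: no organ physiology, no
  plasma-protein binding dynamics, no drug–drug interaction or body-weight
  scaling. Conclusions about absolute exposure inherit the quality of the
  user-supplied `ka`, `CL`, `V`, `F`.
* Wald intervals rely on local linearization; for strongly nonlinear,
  weakly identified families (biexponential on amount-only data) they can
  badly understate asymmetry. Profile or bootstrap intervals are out of
  scope.
* Model selection uses adjusted R² alone, matching the field's practice
  for release data; information criteria are not computed.
* Release-rate observations are treated as instantaneous point rates at
  their stated time; if a label value is actually an interval average the
  induced bias is not corrected.
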