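# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own closed forms: finite differences, quadrature,
# explicit Euler stepping, textbook formulas.

# central finite difference of a scalar function
num_deriv <- function(f, x, h = 1e-4) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# textbook least squares through the origin with Wald/t CI
ols_origin <- function(t, y, level = 0.95) {
  k <- sum(t * y) / sum(t * t)
  rss <- sum((y - k * t)^2)
  df <- length(t) - 1
  se <- sqrt(rss / df / sum(t * t))
  tq <- qt(1 - (1 - level) / 2, df)
  list(k = k, se = se, lower = k - tq * se, upper = k + tq * se, rss = rss)
}

# brute-force explicit Euler integration of the depot + one-compartment
# system under an arbitrary input rate (mg/day); returns conc in pg/mL
euler_conc <- function(input_fn, disp, t_out, dt = 0.005) {
  ka <- disp$ka
  kel <- disp$CL / disp$V
  Fb <- disp$F
  t_end <- max(t_out)
  n <- ceiling(t_end / dt)
  a1 <- 0
  a2 <- 0
  tt <- 0
  out <- numeric(length(t_out))
  j <- 1
  while (j <= length(t_out) && t_out[j] <= 0) {
    out[j] <- 0
    j <- j + 1
  }
  for (i in seq_len(n)) {
    r <- input_fn(tt)
    a1_new <- a1 + dt * (r - ka * a1)
    a2_new <- a2 + dt * (Fb * ka * a1 - kel * a2)
    a1 <- a1_new
    a2 <- a2_new
    tt <- tt + dt
    while (j <= length(t_out) && t_out[j] <= tt + 1e-12) {
      out[j] <- a2 / disp$V * 1e6
      j <- j + 1
    }
  }
  out
}

# closed-form concentration for a mono-exponential implant input
# r(t) = R0 * exp(-k1 t): a sum of three exponentials
triexp_conc <- function(t, R0, k1, disp) {
  ka <- disp$ka
  kel <- disp$CL / disp$V
  Fb <- disp$F
  term <- function(lam, l2, l3) exp(-lam * t) / ((l2 - lam) * (l3 - lam))
  a2 <- Fb * ka * R0 * (
    term(k1, ka, kel) + term(ka, k1, kel) + term(kel, k1, ka)
  )
  a2 / disp$V * 1e6
}

# randomized-but-valid parameter draws per family, for property loops.
# Unbounded (polynomial) families are scaled so Q(1825 days) stays below the
# loaded dose: release data beyond the load would be clipped by the
# generator's physical truncation and no longer follow the curve.
random_params <- function(family, dose = 150, t_max = 1825) {
  switch(family,
    zero_order = list(k = runif(1, 0.005, 0.9 * dose / t_max)),
    first_order = list(Qmax = runif(1, 20, dose), k1 = runif(1, 1e-4, 5e-3)),
    second_order = list(Qmax = runif(1, 20, dose), k2 = runif(1, 1e-7, 1e-4)),
    higuchi = list(kH = runif(1, 0.5, 0.9 * dose / sqrt(t_max))),
    korsmeyer_peppas = {
      n <- runif(1, 0.3, 1.0)
      list(kkp = runif(1, 0.1, 0.9) * dose / t_max^n, n = n)
    },
    hixson_crowell = list(Qhc = runif(1, 40, dose), khc = runif(1, 1e-4, 8e-4)),
    weibull = list(Qmax = runif(1, 20, dose), kw = runif(1, 1e-4, 5e-3), l = runif(1, 0.5, 1.5)),
    biexponential = list(
      Dose = dose, Qb1 = runif(1, 10, dose / 2),
      kb1 = runif(1, 5e-4, 5e-3), kb2 = runif(1, 1e-5, 4e-4)
    ),
    peppas_sahlin = {
      m <- runif(1, 0.3, 0.6)
      list(
        kps1 = runif(1, 0.1, 0.45) * dose / t_max^m,
        kps2 = runif(1, 0.1, 0.45) * dose / t_max^(2 * m),
        m = m
      )
    },
    population_council = list(
      kpc1 = runif(1, 0.2, 0.45 * dose / sqrt(t_max)),
      kpc2 = runif(1, 1e-3, 0.45 * dose / t_max)
    )
  )
}

table2_first_order <- list(Qmax = 67.86, k1 = 9e-4)
table2_biexponential <- list(Dose = 150, Qb1 = 44.64, kb1 = 0.00127, kb2 = 8.985e-5)

# noise-free joint amount + rate observation set from a generating truth
noise_free_obs <- function(family, params, with_rates = FALSE,
                           implant = lng_implant_150()) {
  cfg <- synthetic_config(
    family = family, params = params, implant = implant,
    noise = list(additive_sd = 0), seed = 1
  )
  obs <- generate_ex_vivo(cfg)
  if (with_rates) {
    rates <- generate_label_rates(cfg)
    obs <- observation_set(
      dplyr::bind_rows(
        obs,
        tibble::tibble(
          time_days = rates$time_days, type = "rate",
          value = rates$rate, se = NA_real_, n = NA_integer_
        )
      ),
      implant
    )
  }
  obs
}
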