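#' Default device-removal sampling times
#'
#' Thirteen time points over five years: insertion, quarterly through the
#' first year, then semiannually to day 1825. Device-removal release
#' studies sample on roughly this cadence; the real designs are not
#' published in tabular form, so this schedule is a documented assumption.
#'
#' @return Numeric vector of days, length 13.
#' @export
default_amount_times <- function() {
  c(0, 91.25, 182.5, 273.75, 365, 547.5, 730,
    912.5, 1095, 1277.5, 1460, 1642.5, 1825)
}

#' Configuration for synthetic release/PK data
#'
#' Bundles the generating truth (family, parameters, implant), the sampling
#' design, the noise model and the seed. The defaults emulate the study
#' conditions the analysis assumes: 13 sampling times over 5 years, 5
#' implants per time, additive measurement noise of 2 mg on the remaining
#' amount, and label-style release rates at months 1, 12 and 24.
#'
#' @param family,params,implant The generating truth.
#' @param amount_times Device-removal times, days.
#' @param n_implants_per_time Implants assayed per time point.
#' @param noise One of `list(additive_sd = <mg>)` or
#'   `list(proportional_cv = <fraction>)`, applied to the remaining amount.
#' @param rate_times Times of release-rate records, days.
#' @param rate_noise_sd Additive SD (mg/day) on rate records; default 0
#'   (label rates are quoted without error).
#' @param plasma Optional list for plasma observation generation:
#'   `disposition` ([disposition_params()]), `obs_times` (days),
#'   `proportional_cv` (fraction).
#' @param seed Integer seed; all generators are reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(family = "first_order",
                             params = list(Qmax = 67.86, k1 = 9e-4),
                             implant = lng_implant_150(),
                             amount_times = default_amount_times(),
                             n_implants_per_time = 5L,
                             noise = list(additive_sd = 2),
                             rate_times = months_to_days(c(1, 12, 24)),
                             rate_noise_sd = 0,
                             plasma = NULL,
                             seed = 1L) {
  check_implant(implant)
  validate_params(family, c(as.list(params), if (family == "biexponential" &&
    !"Dose" %in% names(params)) list(Dose = implant$dose_loaded)))
  check_times(amount_times)
  check_times(rate_times)
  if (any(amount_times > 2 * 1825)) {
    abort("Sampling times beyond twice the 5-year horizon are not supported.")
  }
  stopifnot(n_implants_per_time >= 1)
  if (!is.list(noise) || length(noise) != 1 ||
    !names(noise) %in% c("additive_sd", "proportional_cv")) {
    abort("`noise` must be list(additive_sd = ...) or list(proportional_cv = ...).")
  }
  if (noise[[1]] < 0) abort("Noise parameters must be >= 0.")
  stopifnot(rate_noise_sd >= 0)
  structure(
    list(
      family = family, params = as.list(params), implant = implant,
      amount_times = amount_times,
      n_implants_per_time = as.integer(n_implants_per_time),
      noise = noise, rate_times = rate_times, rate_noise_sd = rate_noise_sd,
      plasma = plasma, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

truth_params <- function(config) {
  p <- config$params
  if (config$family == "biexponential" && !"Dose" %in% names(p)) {
    p$Dose <- config$implant$dose_loaded
  }
  p
}

#' Generate a synthetic device-removal dataset
#'
#' For each sampling time, draws `n_implants_per_time` residual-drug
#' values `dose - Q_true(t) + noise`, truncates to `[0, dose]`, and
#' reports the mean released amount, its standard error (`sd/sqrt(n)`),
#' and `n` -- the summary form in which device-removal studies publish
#' their data. With zero noise the means equal `Q_true(t)` exactly. A
#' warning of class `larkin_truncation` is raised if more than half of
#' the draws at any time required truncation.
#'
#' @param config A [synthetic_config()].
#' @return An [observation_set()] of amount observations.
#' @export
generate_ex_vivo <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dose <- config$implant$dose_loaded
  p <- truth_params(config)
  q_true <- suppressWarnings(
    release_amount(config$amount_times, config$family, p)
  )
  n <- config$n_implants_per_time
  rows <- withr::with_seed(config$seed, {
    purrr::map2_dfr(config$amount_times, q_true, function(t, q) {
      remaining_true <- dose - q
      sdev <- if (names(config$noise) == "additive_sd") {
        config$noise$additive_sd
      } else {
        config$noise$proportional_cv * remaining_true
      }
      draws <- remaining_true + rnorm(n, 0, sdev)
      n_trunc <- sum(draws < 0 | draws > dose)
      draws <- pmin(pmax(draws, 0), dose)
      if (n_trunc > n / 2) {
        warn(sprintf(
          "At t = %g days, %d of %d draws were truncated to [0, %g] mg; noise scale is implausible.",
          t, n_trunc, n, dose
        ), class = "larkin_truncation")
      }
      tibble::tibble(
        time_days = t,
        type = "amount",
        value = dose - mean(draws),
        se = sd(draws) / sqrt(n),
        n = n
      )
    })
  })
  observation_set(rows, config$implant)
}

#' Generate label-style release-rate records
#'
#' Evaluates the true release rate at the configured times (default months
#' 1, 12 and 24), optionally adding truncated Gaussian noise.
#'
#' @param config A [synthetic_config()].
#' @return A tibble `time_days`, `rate` (mg/day).
#' @export
generate_label_rates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- truth_params(config)
  rate <- release_rate(config$rate_times, config$family, p)
  if (config$rate_noise_sd > 0) {
    rate <- withr::with_seed(
      config$seed + 1L,
      pmax(rate + rnorm(length(rate), 0, config$rate_noise_sd), 0)
    )
  }
  tibble::tibble(time_days = config$rate_times, rate = rate)
}

#' Generate synthetic plasma concentration observations
#'
#' Simulates the concentration profile at the generating truth and applies
#' proportional measurement error. The reported per-point `error` is
#' `CV * true concentration`, the scale at which the 1.25-fold adequacy
#' rule operates.
#'
#' @param config A [synthetic_config()] whose `plasma` block supplies
#'   `disposition`, `obs_times`, and `proportional_cv`.
#' @return A tibble `time_days`, `conc` (pg/mL), `error` (pg/mL).
#' @export
generate_plasma_observations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pl <- config$plasma
  if (is.null(pl)) abort("`config$plasma` block is required.")
  stopifnot(
    inherits(pl$disposition, "disposition_params"),
    is.numeric(pl$obs_times), pl$proportional_cv >= 0
  )
  input_params <- config$params
  prof <- simulate_concentration(
    config$implant, config$family, input_params, pl$disposition,
    times = sort(unique(c(0, pl$obs_times)))
  )
  conc_true <- prof$conc_pg_ml[match(pl$obs_times, prof$time_days)]
  cv <- pl$proportional_cv
  conc_obs <- withr::with_seed(
    config$seed + 2L,
    conc_true * (1 + rnorm(length(conc_true), 0, cv))
  )
  tibble::tibble(
    time_days = pl$obs_times,
    conc = pmax(conc_obs, 0),
    error = cv * conc_true
  )
}
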