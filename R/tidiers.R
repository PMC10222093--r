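#' Tidy a release-model fit
#'
#' One row per free parameter with estimate, standard error and Wald
#' confidence bounds; fixed parameters (the biexponential `Dose`) are
#' included with `fixed = TRUE` and no uncertainty.
#'
#' @param x A `release_fit`.
#' @param conf.level Confidence level, default from the fit.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `fixed`.
#' @method tidy release_fit
#' @export
tidy.release_fit <- function(x, conf.level = NULL, ...) {
  cis <- parameter_cis(x, level = conf.level)
  out <- tibble::tibble(
    term = cis$term,
    estimate = cis$estimate,
    std.error = cis$se,
    conf.low = cis$lower,
    conf.high = cis$upper,
    fixed = FALSE
  )
  fixed <- setdiff(names(x$estimates), x$free)
  if (length(fixed) > 0) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(
        term = fixed,
        estimate = unlist(x$estimates[fixed]),
        std.error = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
        fixed = TRUE
      )
    )
  }
  out
}

#' Glance at a release-model fit
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family_id`, `sse`, `r.squared`,
#'   `adj.r.squared`, `sigma`, `nobs`, `n_params`, `df.residual`,
#'   `converged`, `rate_weight`.
#' @method glance release_fit
#' @export
glance.release_fit <- function(x, ...) {
  tibble::tibble(
    family_id = x$family,
    sse = x$sse,
    r.squared = x$r2,
    adj.r.squared = x$adjusted_r2,
    sigma = sqrt(x$sigma2),
    nobs = x$n_obs,
    n_params = x$n_params,
    df.residual = x$df,
    converged = x$converged,
    rate_weight = x$options$rate_weight
  )
}

#' Augment release observations with fitted values
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return The observation tibble with `.fitted` and `.resid` columns
#'   (fitted amounts for amount rows, fitted rates for rate rows).
#' @method augment release_fit
#' @export
augment.release_fit <- function(x, ...) {
  dat <- x$data
  fitted <- ifelse(
    dat$type == "amount",
    suppressWarnings(release_amount(dat$time_days, x$family, x$estimates)),
    release_rate(dat$time_days, x$family, x$estimates)
  )
  dplyr::mutate(dat, .fitted = fitted, .resid = .data$value - fitted)
}
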