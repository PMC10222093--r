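#' Wald confidence intervals for fitted parameters
#'
#' Linearized (Wald) intervals `estimate +/- t(df, level) * se`, with
#' standard errors from the covariance `sigma2 * (J'J)^-1` at the optimum.
#' Intervals for poorly identified parameters can span negative values even
#' when the parameter is physically non-negative (common for multi-phase
#' exponential fits to sparse data); such intervals are reported as-is and
#' flagged in the `spans_zero` column rather than truncated.
#'
#' @param fit A `release_fit`.
#' @param level Confidence level; defaults to the level stored in the fit.
#' @return A tibble: `term`, `estimate`, `se`, `lower`, `upper`,
#'   `spans_zero`.
#' @export
parameter_cis <- function(fit, level = NULL) {
  stopifnot(inherits(fit, "release_fit"))
  level <- level %||% fit$ci_level
  stopifnot(level > 0, level < 1)
  if (!fit$converged) {
    warn("Fit did not converge; intervals are unreliable.")
  }
  est <- unlist(fit$estimates[fit$free])
  tq <- qt(1 - (1 - level) / 2, fit$df)
  tibble::tibble(
    term = fit$free,
    estimate = as.numeric(est),
    se = as.numeric(fit$se),
    lower = estimate - tq * se,
    upper = estimate + tq * se,
    spans_zero = lower < 0 & upper > 0
  )
}

#' Delta-method prediction band
#'
#' Pointwise band expected to contain a new noisy observation of the
#' cumulative released amount at each time:
#' `Qhat(t) +/- t(df, level) * sqrt(sigma2 + g' C g)` where `g` is the
#' gradient of Q with respect to the parameters and `C` the parameter
#' covariance. The parameter-uncertainty term grows outside the observed
#' time range, so the band widens under extrapolation.
#'
#' @param fit A converged `release_fit`.
#' @param times Times in days.
#' @param level Band level, default from the fit.
#' @return A tibble: `time_days`, `fit`, `lower`, `upper`.
#' @export
prediction_band <- function(fit, times, level = NULL) {
  stopifnot(inherits(fit, "release_fit"))
  level <- level %||% fit$ci_level
  check_times(times)
  if (!fit$identifiable) {
    warn("Parameter covariance is singular; band reflects residual variance only.")
  }
  qhat <- suppressWarnings(release_amount(times, fit$family, fit$estimates))
  g <- suppressWarnings(
    param_gradient(times, fit$family, fit$estimates, fit$free)
  )
  cov <- fit$cov
  cov[!is.finite(cov)] <- 0
  var_mean <- rowSums((g %*% cov) * g)
  half <- qt(1 - (1 - level) / 2, fit$df) * sqrt(fit$sigma2 + pmax(var_mean, 0))
  tibble::tibble(
    time_days = times,
    fit = qhat,
    lower = qhat - half,
    upper = qhat + half
  )
}

#' Rank competing release-model fits
#'
#' Sorts fits by adjusted R-squared (descending); exact ties go to the
#' model with fewer parameters; fits that did not converge are ranked last
#' and flagged. All fits must be to the same observation set.
#'
#' `compare_models()` also accepts a plain data frame with columns
#' `family_id` and `adjusted_r2` (optional `n_params`, `converged`), so a
#' ranking can be reproduced from reported goodness-of-fit statistics alone.
#'
#' @param x A list of `release_fit` objects, or a data frame as above.
#' @param ... Unused.
#' @return A tibble sorted by rank with columns `rank`, `family_id`,
#'   `adjusted_r2`, `n_params`, `converged` (plus `r2`, `sse` for fit
#'   input).
#' @export
compare_models <- function(x, ...) {
  UseMethod("compare_models")
}

#' @export
compare_models.list <- function(x, ...) {
  stopifnot(length(x) >= 1, all(purrr::map_lgl(x, inherits, "release_fit")))
  key <- function(f) f$data[, c("time_days", "type", "value")]
  ref <- key(x[[1]])
  same <- purrr::map_lgl(x, ~ isTRUE(all.equal(key(.x), ref)))
  if (!all(same)) {
    abort("All fits must be to the same observation set.")
  }
  tab <- purrr::map_dfr(x, function(f) {
    tibble::tibble(
      family_id = f$family,
      adjusted_r2 = f$adjusted_r2,
      r2 = f$r2,
      sse = f$sse,
      n_params = f$n_params,
      converged = f$converged
    )
  })
  rank_model_table(tab)
}

#' @export
compare_models.data.frame <- function(x, ...) {
  need <- c("family_id", "adjusted_r2")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Need column(s): %s.", paste(missing, collapse = ", ")))
  }
  tab <- tibble::as_tibble(x)
  if (!"n_params" %in% names(tab)) tab$n_params <- NA_integer_
  if (!"converged" %in% names(tab)) tab$converged <- TRUE
  rank_model_table(tab)
}

rank_model_table <- function(tab) {
  out <- dplyr::arrange(
    tab,
    dplyr::desc(.data$converged),
    dplyr::desc(.data$adjusted_r2),
    .data$n_params
  )
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}
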