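# Parameter roles drive the automatic starting values and box bounds:
#   amount      mg, asymptote-like            -> start 0.5 * dose, (0, dose]
#   day_rate    1/day exponential constants   -> start near 1/t_max, [1e-7, 1]
#   exponent    dimensionless                 -> start 0.5, [1e-3, 10]
#   coefficient mg/day^x polynomial scales    -> start from data scale
.param_roles <- list(
  amount = c("Qmax", "Qb1", "Qhc"),
  day_rate = c("k1", "kw", "kb1", "kb2"),
  exponent = c("l", "n", "m"),
  coefficient = c("k", "kH", "kkp", "kps1", "kps2", "kpc1", "kpc2")
)

#' Fitting options
#'
#' @param starting_values `"auto"` (data-scaled defaults) or a named list of
#'   starting values for the free parameters.
#' @param lower,upper Optional named vectors overriding the default box
#'   bounds.
#' @param rate_weight Weight of squared rate residuals relative to squared
#'   amount residuals in the objective. `"auto"` scales so that one rate
#'   observation contributes comparably to one amount observation
#'   (weight = (mean observed amount / mean observed rate)^2); a number
#'   fixes it directly; `0` ignores rate observations.
#' @param max_iterations Optimizer iteration cap.
#' @param tol Convergence tolerance on the cost function.
#' @param ci_level Default confidence level for Wald intervals.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(starting_values = "auto", lower = NULL, upper = NULL,
                        rate_weight = "auto", max_iterations = 500L,
                        tol = 1e-10, ci_level = 0.95) {
  stopifnot(tol > 0, ci_level > 0, ci_level < 1, max_iterations >= 1)
  if (!identical(rate_weight, "auto")) {
    assert_scalar_number(rate_weight, "rate_weight", lower = 0)
  }
  structure(
    list(
      starting_values = starting_values, lower = lower, upper = upper,
      rate_weight = rate_weight, max_iterations = as.integer(max_iterations),
      tol = tol, ci_level = ci_level
    ),
    class = "fit_options"
  )
}

# starting value / bound tables for one family given the data scale
auto_setup <- function(family, obs, implant) {
  free <- free_parameters(family)
  t_max <- max(obs$time_days, 1)
  q_scale <- max(obs$value[obs$type == "amount"], 1e-3)
  dose <- implant$dose_loaded
  start <- numeric(0)
  lower <- numeric(0)
  upper <- numeric(0)
  for (nm in free) {
    if (nm %in% .param_roles$amount) {
      s <- 0.5 * dose
      lo <- 1e-6
      hi <- dose
    } else if (nm %in% .param_roles$day_rate) {
      s <- 1 / t_max
      lo <- 1e-7
      hi <- 1
    } else if (nm %in% .param_roles$exponent) {
      s <- 0.5
      lo <- 1e-3
      hi <- 10
    } else if (nm == "k2") { # second-order, 1/(mg day)
      s <- 1 / (t_max * 0.5 * dose)
      lo <- 1e-12
      hi <- 1
    } else if (nm == "khc") { # mg^(1/3)/day; depletion at t_max when starting
      s <- (0.5 * dose)^(1 / 3) / t_max
      lo <- 1e-7
      hi <- 10
    } else { # polynomial coefficients, scale from the data
      expo <- switch(nm,
        k = 1, kH = 0.5, kkp = 0.5, kps1 = 0.5, kps2 = 1, kpc1 = 0.5, kpc2 = 1,
        1
      )
      s <- q_scale / t_max^expo
      lo <- 1e-10
      hi <- 1e3
    }
    start[nm] <- s
    lower[nm] <- lo
    upper[nm] <- hi
  }
  # a biexponential started with equal rate constants has two identical
  # components (singular Jacobian); stagger the phases around 1/t_max
  if (family == "biexponential") {
    start["kb1"] <- min(10 / t_max, 1)
    start["kb2"] <- 0.1 / t_max
  }
  list(start = start, lower = lower, upper = upper)
}

# full parameter list = free values + fixed values (biexponential Dose)
full_params <- function(family, free_values, implant) {
  def <- family_def(family)
  p <- as.list(free_values)
  if ("Dose" %in% def$fixed) p$Dose <- implant$dose_loaded
  p[def$parameters]
}

split_obs <- function(obs) {
  list(
    amount = obs[obs$type == "amount", , drop = FALSE],
    rate = obs[obs$type == "rate", , drop = FALSE]
  )
}

resolve_rate_weight <- function(rate_weight, parts) {
  if (!identical(rate_weight, "auto")) {
    return(rate_weight)
  }
  if (nrow(parts$rate) == 0 || nrow(parts$amount) == 0) {
    return(1)
  }
  (mean(parts$amount$value) / mean(parts$rate$value))^2
}

# weighted residual vector: c(amount residuals, sqrt(w) * rate residuals)
resid_vector <- function(free_values, family, parts, implant, rate_weight) {
  p <- full_params(family, free_values, implant)
  r_amt <- numeric(0)
  r_rate <- numeric(0)
  if (nrow(parts$amount) > 0) {
    r_amt <- parts$amount$value -
      suppressWarnings(release_amount(parts$amount$time_days, family, p))
  }
  if (nrow(parts$rate) > 0 && rate_weight > 0) {
    r_rate <- sqrt(rate_weight) *
      (parts$rate$value - release_rate(parts$rate$time_days, family, p))
  }
  c(r_amt, r_rate)
}

# gradient of the release *rate* with respect to free parameters; analytic
# for the families whose registry carries closed-form gradients, central
# finite differences otherwise
rate_gradient <- function(t, family, params, free) {
  p <- validate_params(family, params)
  if (family == "first_order") {
    e <- exp(-p$k1 * t)
    return(cbind(
      Qmax = p$k1 * e,
      k1 = p$Qmax * e * (1 - p$k1 * t)
    )[, free, drop = FALSE])
  }
  if (family == "biexponential") {
    e1 <- exp(-p$kb1 * t)
    e2 <- exp(-p$kb2 * t)
    return(cbind(
      Dose = p$kb2 * e2,
      Qb1 = p$kb1 * e1 - p$kb2 * e2,
      kb1 = p$Qb1 * e1 * (1 - p$kb1 * t),
      kb2 = (p$Dose - p$Qb1) * e2 * (1 - p$kb2 * t)
    )[, free, drop = FALSE])
  }
  if (family == "zero_order") {
    return(cbind(k = rep(1, length(t)))[, free, drop = FALSE])
  }
  if (family == "higuchi") {
    return(cbind(kH = 1 / (2 * sqrt(t)))[, free, drop = FALSE])
  }
  if (family == "population_council") {
    return(cbind(kpc1 = 1 / (2 * sqrt(t)), kpc2 = rep(1, length(t)))[, free, drop = FALSE])
  }
  def <- family_def(family)
  g <- matrix(0, length(t), length(free), dimnames = list(NULL, free))
  for (nm in free) {
    h <- max(abs(p[[nm]]), 1e-4) * 1e-6
    up <- p
    dn <- p
    up[[nm]] <- p[[nm]] + h
    dn[[nm]] <- max(p[[nm]] - h, 0)
    hh <- up[[nm]] - dn[[nm]]
    g[, nm] <- (def$dq(t, up) - def$dq(t, dn)) / hh
  }
  g
}

# Jacobian of the weighted residual vector (n_res x p); residuals are
# data - model, so the Jacobian is minus the model gradients
resid_jacobian <- function(free_values, family, parts, implant, rate_weight) {
  free <- names(free_values)
  p <- full_params(family, free_values, implant)
  blocks <- list()
  if (nrow(parts$amount) > 0) {
    blocks$amt <- -param_gradient(parts$amount$time_days, family, p, free)
  }
  if (nrow(parts$rate) > 0 && rate_weight > 0) {
    blocks$rate <- -sqrt(rate_weight) *
      rate_gradient(parts$rate$time_days, family, p, free)
  }
  do.call(rbind, blocks)
}

# families for which the residual Jacobian is fully analytic
.analytic_jac <- c(
  "first_order", "biexponential", "zero_order", "higuchi",
  "population_council"
)

#' Weighted sum-of-squares objective
#'
#' The quantity the fit minimizes: the sum of squared amount residuals plus
#' `rate_weight` times the sum of squared rate residuals,
#' `sum((q - Q(t))^2) + w * sum((r - dQ/dt(t))^2)`.
#' Parameter values that are invalid for the family yield `+Inf` (with a
#' warning), so the objective is safe to hand to an optimizer.
#'
#' @param data An [observation_set()] or data frame with `time_days`, `type`,
#'   `value`.
#' @param family Family id.
#' @param params Named parameters (free parameters; a fixed `Dose` is taken
#'   from the implant).
#' @param rate_weight Non-negative weight on rate residuals.
#' @param implant An [implant_spec()]; defaults to the one attached to `data`.
#' @return A single non-negative number (or `+Inf` for invalid parameters).
#' @export
objective_sse <- function(data, family, params, rate_weight = 1,
                          implant = NULL) {
  implant <- obs_implant(data, implant)
  if (nrow(data) == 0) abort("`data` must contain at least one observation.")
  parts <- split_obs(data)
  free <- free_parameters(family)
  fv <- unlist(as.list(params)[intersect(names(params), free)])
  tryCatch(
    sum(resid_vector(fv, family, parts, implant, rate_weight)^2),
    error = function(e) {
      warn(sprintf("objective_sse: invalid parameters (%s); returning Inf.", conditionMessage(e)))
      Inf
    }
  )
}

#' Fit a release-kinetics model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) of one model family to an observation set,
#' jointly over cumulative-amount and release-rate observations. Analytic
#' residual Jacobians are used for families with closed-form parameter
#' gradients; the optimizer's finite differences otherwise.
#'
#' Standard errors and confidence intervals are linearized (Wald):
#' covariance `sigma2 * (J'J)^-1` with `sigma2 = SSE / (n - p)` and
#' t-quantiles. R-squared uses the total sum of squares of the *amount*
#' observations only (rate observations enter the SSE as auxiliary data but
#' not the SST); this matters when comparing families on mixed data and is
#' deliberate.
#'
#' @inheritParams objective_sse
#' @param options A [fit_options()] list.
#' @return An object of class `release_fit`; see [tidy.release_fit()] and
#'   [glance.release_fit()] for tabular views.
#' @examples
#' imp <- lng_implant_150()
#' times <- c(91, 183, 274, 365, 548, 730, 1095, 1460, 1825)
#' q <- release_amount(times, "first_order", list(Qmax = 67.86, k1 = 9e-4))
#' obs <- observation_set(
#'   data.frame(time_days = times, type = "amount", value = q), imp
#' )
#' fit <- fit_release_model(obs, "first_order")
#' glance(fit)
#' @export
fit_release_model <- function(data, family, implant = NULL,
                              options = fit_options()) {
  implant <- obs_implant(data, implant)
  def <- family_def(family)
  parts <- split_obs(data)
  rate_weight <- resolve_rate_weight(options$rate_weight, parts)
  n_res <- nrow(parts$amount) +
    if (rate_weight > 0) nrow(parts$rate) else 0L
  free <- free_parameters(family)
  p <- length(free)
  if (n_res - p < 1) {
    abort(sprintf(
      "Insufficient data: %d observations for %d free parameters (need at least %d).",
      n_res, p, p + 1
    ))
  }

  setup <- auto_setup(family, data, implant)
  start <- setup$start
  if (!identical(options$starting_values, "auto")) {
    sv <- unlist(options$starting_values)
    start[names(sv)] <- sv
  }
  lower <- setup$lower
  upper <- setup$upper
  if (!is.null(options$lower)) lower[names(options$lower)] <- options$lower
  if (!is.null(options$upper)) upper[names(options$upper)] <- options$upper
  start <- pmin(pmax(start, lower), upper)

  fn <- function(par) {
    tryCatch(
      resid_vector(setNames(par, free), family, parts, implant, rate_weight),
      error = function(e) rep(1e10, n_res)
    )
  }
  jac <- NULL
  if (family %in% .analytic_jac) {
    jac <- function(par) {
      resid_jacobian(setNames(par, free), family, parts, implant, rate_weight)
    }
  }
  lm_args <- list(
    par = start, fn = fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = min(options$max_iterations, 1024L),
      ftol = options$tol, ptol = 1e-12, gtol = 0
    )
  )
  if (!is.null(jac)) lm_args$jac <- jac
  # minpack emits a warning on iteration exhaustion; the same information is
  # carried in the converged flag and info code
  lm <- suppressWarnings(do.call(minpack.lm::nls.lm, lm_args))

  est_free <- setNames(as.numeric(lm$par), free)
  estimates <- full_params(family, est_free, implant)
  res <- fn(est_free)
  sse <- sum(res^2)
  df <- n_res - p
  sigma2 <- sse / df
  converged <- lm$info %in% 1:3

  J <- resid_jacobian(est_free, family, parts, implant, rate_weight)
  jtj <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(jtj), error = function(e) NULL)
  identifiable <- !is.null(cov)
  if (!identifiable) {
    warn(sprintf(
      "Curvature matrix is singular for family '%s'; standard errors are undefined.",
      family
    ))
    cov <- matrix(NA_real_, p, p, dimnames = list(free, free))
  } else {
    dimnames(cov) <- list(free, free)
  }
  se <- sqrt(pmax(diag(cov), 0))
  tq <- qt(1 - (1 - options$ci_level) / 2, df)
  ci <- cbind(lower = est_free - tq * se, upper = est_free + tq * se)

  q_amt <- parts$amount$value
  sst <- if (length(q_amt) >= 2) sum((q_amt - mean(q_amt))^2) else NA_real_
  r2 <- if (isTRUE(sst > 0)) 1 - sse / sst else NA_real_
  adj_r2 <- if (!is.na(r2) && n_res - p - 1 >= 1) {
    adjusted_r_squared(sse, sst, n_res, p)
  } else {
    NA_real_
  }

  structure(
    list(
      family = family, implant = implant,
      estimates = estimates, free = free,
      se = se, ci = ci, ci_level = options$ci_level,
      sse = sse, sst = sst, r2 = r2, adjusted_r2 = adj_r2,
      n_obs = n_res, n_params = p, df = df, sigma2 = sigma2,
      cov = cov, identifiable = identifiable,
      converged = converged, info = lm$info, message = lm$message,
      niter = lm$niter,
      options = list(
        starting_values = start, lower = lower, upper = upper,
        rate_weight = rate_weight, max_iterations = options$max_iterations,
        tol = options$tol, ci_level = options$ci_level
      ),
      data = tibble::as_tibble(data)
    ),
    class = "release_fit"
  )
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf(
    "<release_fit> %s on %d observation(s)%s\n", x$family, x$n_obs,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  est <- unlist(x$estimates[x$free])
  for (nm in x$free) {
    cat(sprintf(
      "  %-5s %.6g  (%g%% CI %.6g, %.6g)\n", nm, est[[nm]],
      100 * x$ci_level, x$ci[nm, "lower"], x$ci[nm, "upper"]
    ))
  }
  cat(sprintf(
    "  SSE = %.6g, R2 = %.4f, adjusted R2 = %.4f\n",
    x$sse, x$r2, x$adjusted_r2
  ))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `R2 = 1 - sse/sst`, penalized for model size:
#' `1 - (1 - R2) * (n_obs - 1) / (n_obs - n_params - 1)`. This is the
#' goodness-of-fit statistic used to rank release models.
#'
#' @param sse Residual sum of squares (>= 0).
#' @param sst Total sum of squares about the mean of the amount
#'   observations (> 0).
#' @param n_obs Number of observations.
#' @param n_params Number of free model parameters.
#' @return A single number (<= 1; can be negative for terrible fits).
#' @examples
#' adjusted_r_squared(sse = 1, sst = 10, n_obs = 10, n_params = 2)
#' @export
adjusted_r_squared <- function(sse, sst, n_obs, n_params) {
  stopifnot(sse >= 0, n_params >= 0)
  if (!isTRUE(sst > 0)) abort("`sst` must be > 0.")
  if (n_obs - n_params - 1 < 1) {
    abort(sprintf(
      "Degenerate degrees of freedom: n_obs = %d, n_params = %d.",
      n_obs, n_params
    ))
  }
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n_obs - 1) / (n_obs - n_params - 1)
}

#' Predicted cumulative release from a fit
#'
#' @param object A `release_fit`.
#' @param times Times in days; defaults to the observed amount times.
#' @param what `"amount"` (mg) or `"rate"` (mg/day).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.release_fit <- function(object, times = NULL, what = c("amount", "rate"), ...) {
  what <- match.arg(what)
  times <- times %||% object$data$time_days[object$data$type == "amount"]
  if (what == "amount") {
    suppressWarnings(release_amount(times, object$family, object$estimates))
  } else {
    release_rate(times, object$family, object$estimates)
  }
}
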