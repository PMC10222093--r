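#' Convert residual drug in the device to cumulative released amount
#'
#' Device-removal (ex vivo) studies report the drug still inside the
#' explanted device; the released amount is the loaded dose minus that
#' residual. The per-timepoint standard error is unchanged by the
#' conversion (linear transform with unit slope).
#'
#' @param remaining Residual drug in mg (vectorized).
#' @param implant An [implant_spec()].
#' @return Released amount in mg.
#' @examples
#' residual_to_released(82.14, lng_implant_150()) # 67.86
#' @export
residual_to_released <- function(remaining, implant) {
  check_implant(implant)
  if (any(remaining < 0) || any(remaining > implant$dose_loaded)) {
    abort(sprintf(
      "Residual amounts must lie in [0, %g] mg for %s (loaded dose).",
      implant$dose_loaded, implant$name
    ))
  }
  implant$dose_loaded - remaining
}

#' @rdname residual_to_released
#' @param released Released amount in mg.
#' @export
released_to_residual <- function(released, implant) {
  check_implant(implant)
  if (any(released < 0) || any(released > implant$dose_loaded)) {
    abort(sprintf(
      "Released amounts must lie in [0, %g] mg for %s (loaded dose).",
      implant$dose_loaded, implant$name
    ))
  }
  implant$dose_loaded - released
}

#' Integrate piecewise release rates into a cumulative amount curve
#'
#' Product labels state release rates at a few time marks (e.g. 0.1 mg/day
#' at month 1, 0.04 mg/day at 12 months, 0.03 mg/day from 24 months on).
#' This integrates an interpolation of those rates into a cumulative
#' released-amount curve: linear interpolation between the stated rates
#' with constant extrapolation before the first and after the last record
#' (`method = "linear"`, default), or a piecewise-constant (step) reading
#' (`method = "constant"`).
#'
#' @param data Data frame with columns `time_days` (sorted, unique) and
#'   `rate` (mg/day, >= 0).
#' @param t_grid Times (days, >= 0) at which the cumulative amount is
#'   evaluated.
#' @param method `"linear"` or `"constant"`.
#' @return A tibble `time_days`, `cumulative` (mg, non-decreasing, 0 at
#'   t = 0). Empty input gives an empty tibble.
#' @examples
#' rates_to_cumulative(
#'   data.frame(time_days = 30, rate = 0.1), t_grid = 30
#' ) # 3 mg
#' @export
rates_to_cumulative <- function(data, t_grid, method = c("linear", "constant")) {
  method <- match.arg(method)
  if (nrow(data) == 0) {
    return(tibble::tibble(time_days = numeric(0), cumulative = numeric(0)))
  }
  stopifnot(all(c("time_days", "rate") %in% names(data)))
  tt <- data$time_days
  rr <- data$rate
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("Rate records must be sorted by time with no duplicates.")
  }
  if (any(rr < 0)) abort("Rates must be >= 0 mg/day.")
  check_times(t_grid)
  knots <- sort(unique(c(0, tt, t_grid)))
  f <- if (length(tt) == 1L) {
    function(x) rep(rr, length(x)) # single record: constant rate throughout
  } else if (method == "linear") {
    approxfun(tt, rr, method = "linear", rule = 2)
  } else {
    approxfun(tt, rr, method = "constant", rule = 2, f = 0)
  }
  if (method == "linear") {
    vals <- f(knots)
    seg <- diff(knots) * (head(vals, -1) + tail(vals, -1)) / 2
  } else {
    seg <- diff(knots) * f(head(knots, -1))
  }
  cum <- c(0, cumsum(seg))
  tibble::tibble(
    time_days = t_grid,
    cumulative = cum[match(t_grid, knots)]
  )
}

#' Read a release dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `time`,
#' `time_unit` (`day` or `month`), `observation_type` (`amount`, `rate` or
#' `remaining`), `value`, and optional `se`, `n`. Month times are converted
#' to days at 30.44 days/month; `remaining` rows are converted to released
#' amounts against the implant's loaded dose. Rows violating the schema are
#' rejected with their row number rather than coerced.
#'
#' @param path CSV path.
#' @param implant An [implant_spec()].
#' @return An [observation_set()].
#' @examples
#' # synthetic five-year dataset shipped with the package
#' path <- system.file("extdata", "synthetic_release_fiveyear.csv",
#'   package = "larkin"
#' )
#' obs <- read_release_dataset(path, lng_implant_150())
#' dplyr::count(obs, type)
#' @export
read_release_dataset <- function(path, implant) {
  check_implant(implant)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "time_unit", "observation_type", "value")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "Dataset %s is missing column(s): %s.", path,
      paste(missing, collapse = ", ")
    ))
  }
  bad_unit <- which(!raw$time_unit %in% c("day", "month"))
  if (length(bad_unit) > 0) {
    abort(sprintf("Row %d: unknown time_unit '%s'.", bad_unit[1], raw$time_unit[bad_unit[1]]))
  }
  bad_type <- which(!raw$observation_type %in% c("amount", "rate", "remaining"))
  if (length(bad_type) > 0) {
    abort(sprintf(
      "Row %d: unknown observation_type '%s'.",
      bad_type[1], raw$observation_type[bad_type[1]]
    ))
  }
  bad_val <- which(!is.finite(raw$value) | raw$value < 0)
  if (length(bad_val) > 0) {
    abort(sprintf("Row %d: value must be a non-negative number.", bad_val[1]))
  }
  bad_t <- which(!is.finite(raw$time) | raw$time < 0)
  if (length(bad_t) > 0) {
    abort(sprintf("Row %d: time must be a non-negative number.", bad_t[1]))
  }
  t_days <- ifelse(raw$time_unit == "month", months_to_days(raw$time), raw$time)
  value <- raw$value
  type <- raw$observation_type
  is_rem <- type == "remaining"
  if (any(is_rem)) {
    over <- which(is_rem & value > implant$dose_loaded)
    if (length(over) > 0) {
      abort(sprintf(
        "Row %d: remaining amount %g mg exceeds the loaded dose (%g mg).",
        over[1], value[over[1]], implant$dose_loaded
      ))
    }
    value[is_rem] <- residual_to_released(value[is_rem], implant)
    type[is_rem] <- "amount"
  }
  observation_set(
    tibble::tibble(
      time_days = t_days,
      type = type,
      value = value,
      se = if ("se" %in% names(raw)) raw$se else NA_real_,
      n = if ("n" %in% names(raw)) raw$n else NA_integer_
    ),
    implant
  )
}

#' Write a release dataset to CSV
#'
#' Inverse of [read_release_dataset()]: writes the canonical schema with
#' times in days.
#'
#' @param data An [observation_set()] or compatible data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_release_dataset <- function(data, path) {
  out <- tibble::tibble(
    time = data$time_days,
    time_unit = "day",
    observation_type = data$type,
    value = data$value,
    se = data$se,
    n = data$n
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write and read a multi-model fit report
#'
#' Serializes a list of `release_fit` objects to a JSON report: one entry
#' per family (estimates, standard errors, confidence intervals, SSE,
#' R-squared, adjusted R-squared, convergence, the resolved fitting
#' options) plus the adjusted-R-squared ranking from [compare_models()].
#' Numeric fields survive the round trip at full precision.
#'
#' @param fits Non-empty list of `release_fit` objects on one dataset.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  stopifnot(length(fits) >= 1)
  ranking <- compare_models(fits)
  models <- purrr::map(fits, function(f) {
    list(
      family_id = f$family,
      estimates = f$estimates,
      se = as.list(setNames(as.numeric(f$se), f$free)),
      ci = purrr::map(f$free, ~ as.numeric(f$ci[.x, ])) |> setNames(f$free),
      ci_level = f$ci_level,
      sse = f$sse,
      r2 = f$r2,
      adjusted_r2 = f$adjusted_r2,
      n_obs = f$n_obs,
      n_params = f$n_params,
      converged = f$converged,
      options = f$options[c("rate_weight", "max_iterations", "tol", "ci_level")]
    )
  })
  jsonlite::write_json(
    list(models = models, ranking = ranking),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$ranking <- dplyr::bind_rows(purrr::map(doc$ranking, tibble::as_tibble))
  doc
}
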