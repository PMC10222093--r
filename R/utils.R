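# days per calendar month used for label-style time stamps ("month 1",
# "12 months"); 365.25 / 12 rounded to two decimals, stated in the docs
# because product labels never give their own convention.
DAYS_PER_MONTH <- 30.44

#' Convert months to days
#'
#' Long-acting implant labels quote release rates at month marks ("0.1 mg/day
#' at month 1"). All internal computation uses a day time base; these helpers
#' convert at a fixed 30.44 days/month.
#'
#' @param months,days Numeric vectors.
#' @return Numeric vector of days (or months).
#' @examples
#' months_to_days(12) # 365.28
#' @export
months_to_days <- function(months) {
  months * DAYS_PER_MONTH
}

#' @rdname months_to_days
#' @export
days_to_months <- function(days) {
  days / DAYS_PER_MONTH
}

# single check helper used by constructors
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g%s (got %g).", name,
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")", x
    ))
  }
  invisible(x)
}
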