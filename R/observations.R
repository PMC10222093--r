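#' Assemble a release observation set
#'
#' The canonical tabular container for release data: one row per observation
#' with columns `time_days`, `type` (`"amount"` for cumulative released mg,
#' `"rate"` for mg/day), `value`, and optional `se` (standard error, mg) and
#' `n` (number of implants averaged). Amount observations are the mean
#' cumulative released amount across devices explanted at that time; rate
#' observations typically come from a product label's stated release rates.
#'
#' @param data A data frame with at least `time_days`, `type`, `value`.
#' @param implant An [implant_spec()]; attached as an attribute and used to
#'   validate that amounts do not exceed the loaded dose.
#' @return A tibble of class `observation_set` with the implant attached as
#'   attribute `"implant"`.
#' @examples
#' obs <- observation_set(
#'   data.frame(time_days = c(0, 365), type = "amount", value = c(0, 19)),
#'   lng_implant_150()
#' )
#' @export
observation_set <- function(data, implant) {
  check_implant(implant)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("time_days", "type", "value")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`data` is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  if (!"se" %in% names(out)) out$se <- NA_real_
  if (!"n" %in% names(out)) out$n <- NA_integer_
  out <- dplyr::select(out, "time_days", "type", "value", "se", "n")
  if (any(!out$type %in% c("amount", "rate"))) {
    bad <- unique(setdiff(out$type, c("amount", "rate")))
    abort(sprintf("Unknown observation type(s): %s.", paste(bad, collapse = ", ")))
  }
  if (any(out$time_days < 0)) abort("Observation times must be >= 0 days.")
  amt <- out$value[out$type == "amount"]
  if (any(amt < 0) || any(amt > implant$dose_loaded)) {
    abort(sprintf(
      "Amount observations must lie in [0, %g] mg (loaded dose of %s).",
      implant$dose_loaded, implant$name
    ))
  }
  if (any(out$value[out$type == "rate"] < 0)) {
    abort("Rate observations must be >= 0 mg/day.")
  }
  if (any(!is.na(out$se) & out$se < 0)) abort("Standard errors must be >= 0.")
  attr(out, "implant") <- implant
  class(out) <- c("observation_set", class(out))
  out
}

obs_implant <- function(obs, implant = NULL) {
  implant <- implant %||% attr(obs, "implant")
  if (is.null(implant)) {
    abort("No implant spec: supply `implant` or build the data with `observation_set()`.")
  }
  check_implant(implant)
  implant
}
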