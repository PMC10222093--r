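#' Remaining releasable drug in the device
#'
#' The implant input functions used for plasma simulation describe the drug
#' amount still available for release at time `t`, corrected by the
#' releasable fraction `(1 - f)`:
#'
#' * first-order: `L(t) = (1 - f) * Dose * exp(-k1 * t)`
#' * biexponential: `L(t) = (1 - f) * (Qb1 * exp(-kb1 * t) +
#'   (Dose - Qb1) * exp(-kb2 * t))`
#'
#' Both are monotone non-increasing with `L(0) = (1 - f) * Dose`. Only the
#' two exponential families have this closed form; other families are not
#' supported as input functions.
#'
#' The biexponential form applies `(1 - f)` to both exponential terms. When
#' the fitted `Qb1` was estimated with the full load as asymptote, this
#' double-counts the correction; set `rescale_qb1 = TRUE` to instead rescale
#' the phase amounts so that the releasable total is `(1 - f) * Dose` while
#' the phase split `Qb1 : (Dose - Qb1)` is preserved. Numerically the two
#' readings coincide (both scale the whole curve by `(1 - f)`); the switch
#' exists to make the convention explicit and auditable.
#'
#' @param t Times in days, `>= 0`. Vectorized.
#' @param implant An [implant_spec()] (supplies `Dose = dose_loaded` and `f`).
#' @param family `"first_order"` or `"biexponential"`.
#' @param params Named parameters: `k1` (first-order) or `Qb1`, `kb1`, `kb2`
#'   (biexponential). A `Qmax` or `Dose` entry, if present, is ignored in
#'   favour of the implant's loaded dose.
#' @param rescale_qb1 Biexponential convention switch, see Details.
#' @return Numeric vector, mg.
#' @examples
#' imp <- lng_implant_150()
#' remaining_releasable(0, imp, "first_order", list(k1 = 9e-4)) # 75 mg
#' @export
remaining_releasable <- function(t, implant, family, params,
                                 rescale_qb1 = FALSE) {
  check_times(t)
  check_implant(implant)
  dose <- implant$dose_loaded
  avail <- (1 - implant$f) * dose
  p <- as.list(params)
  if (family == "first_order") {
    if (is.null(p$k1) || p$k1 < 0) abort("first_order input needs `k1` >= 0.")
    return(avail * exp(-p$k1 * t))
  }
  if (family == "biexponential") {
    need <- c("Qb1", "kb1", "kb2")
    if (!all(need %in% names(p))) {
      abort("biexponential input needs `Qb1`, `kb1`, `kb2`.")
    }
    if (p$Qb1 < 0 || p$Qb1 > dose) abort("`Qb1` must lie in [0, Dose].")
    if (p$kb1 < 0 || p$kb2 < 0) abort("Rate constants must be >= 0.")
    if (rescale_qb1) {
      # preserve the fitted phase split, rescale totals to (1 - f) * Dose
      q1 <- avail * p$Qb1 / dose
      q2 <- avail * (dose - p$Qb1) / dose
      return(q1 * exp(-p$kb1 * t) + q2 * exp(-p$kb2 * t))
    }
    return((1 - implant$f) *
      (p$Qb1 * exp(-p$kb1 * t) + (dose - p$Qb1) * exp(-p$kb2 * t)))
  }
  abort(sprintf(
    "Input functions are defined for families 'first_order' and 'biexponential', not '%s'.",
    family
  ))
}

#' Implant input rate into the subcutaneous depot
#'
#' Minus the time derivative of [remaining_releasable()]: the instantaneous
#' rate (mg/day) at which drug leaves the device. Its integral over
#' `[0, Inf)` equals the total releasable amount `(1 - f) * Dose`.
#'
#' @inheritParams remaining_releasable
#' @return Numeric vector, mg/day (non-negative).
#' @examples
#' imp <- lng_implant_150()
#' implant_input_rate(0, imp, "first_order", list(k1 = 9e-4)) # 0.0675 mg/day
#' @export
implant_input_rate <- function(t, implant, family, params,
                               rescale_qb1 = FALSE) {
  check_times(t)
  check_implant(implant)
  dose <- implant$dose_loaded
  avail <- (1 - implant$f) * dose
  p <- as.list(params)
  if (family == "first_order") {
    if (is.null(p$k1) || p$k1 < 0) abort("first_order input needs `k1` >= 0.")
    return(avail * p$k1 * exp(-p$k1 * t))
  }
  if (family == "biexponential") {
    need <- c("Qb1", "kb1", "kb2")
    if (!all(need %in% names(p))) {
      abort("biexponential input needs `Qb1`, `kb1`, `kb2`.")
    }
    if (rescale_qb1) {
      q1 <- avail * p$Qb1 / dose
      q2 <- avail * (dose - p$Qb1) / dose
    } else {
      q1 <- (1 - implant$f) * p$Qb1
      q2 <- (1 - implant$f) * (dose - p$Qb1)
    }
    return(p$kb1 * q1 * exp(-p$kb1 * t) + p$kb2 * q2 * exp(-p$kb2 * t))
  }
  abort(sprintf(
    "Input functions are defined for families 'first_order' and 'biexponential', not '%s'.",
    family
  ))
}
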