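#' Describe an implant product
#'
#' An implant spec carries the product identity and the quantities every other
#' operation needs: total loaded dose, number of rods, and the complement `f`
#' of the releasable fraction. Ex vivo residual-drug data show that only part
#' of the loaded dose is ever released; the fraction available for release is
#' `(1 - f)`, so the asymptotic releasable amount is `(1 - f) * dose_loaded`.
#'
#' @param name Product name.
#' @param dose_loaded Total drug loaded in the device, mg. Must be > 0.
#' @param n_rods Number of rods making up the device (>= 1).
#' @param f Complement of the releasable fraction, dimensionless in `[0, 1)`.
#'   `f = 0.5` means half the load is releasable.
#' @return An object of class `implant_spec`.
#' @examples
#' implant_spec("two-rod LNG implant", dose_loaded = 150, n_rods = 2, f = 0.5)
#' @export
implant_spec <- function(name, dose_loaded, n_rods = 1L, f = 0.5) {
  stopifnot(is.character(name), length(name) == 1L)
  assert_scalar_number(dose_loaded, "dose_loaded", lower = 0, closed_lower = FALSE)
  assert_scalar_number(n_rods, "n_rods", lower = 1)
  if (n_rods != as.integer(n_rods)) abort("`n_rods` must be a whole number.")
  assert_scalar_number(f, "f", lower = 0, upper = 1, closed_upper = FALSE)
  structure(
    list(
      name = name,
      dose_loaded = dose_loaded,
      n_rods = as.integer(n_rods),
      f = f
    ),
    class = "implant_spec"
  )
}

#' Two-rod 150 mg levonorgestrel implant
#'
#' Convenience constructor for the reference product used throughout the
#' examples: a two-rod subcutaneous device loaded with 150 mg levonorgestrel,
#' of which half is assumed releasable (`f = 0.5`, from end-of-trial residual
#' drug measurements).
#'
#' @param f Complement of the releasable fraction; default 0.5.
#' @return An `implant_spec`.
#' @export
lng_implant_150 <- function(f = 0.5) {
  implant_spec("LNG-150", dose_loaded = 150, n_rods = 2L, f = f)
}

#' @export
print.implant_spec <- function(x, ...) {
  cat(sprintf(
    "<implant_spec> %s: %g mg in %d rod(s), releasable fraction (1 - f) = %g\n",
    x$name, x$dose_loaded, x$n_rods, 1 - x$f
  ))
  invisible(x)
}

is_implant_spec <- function(x) inherits(x, "implant_spec")

check_implant <- function(implant) {
  if (!is_implant_spec(implant)) {
    abort("`implant` must be created with `implant_spec()`.")
  }
  invisible(implant)
}
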