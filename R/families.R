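# Registry of the ten release-kinetics families.
#
# Every family exposes a closed-form cumulative release Q(t) (mg) and its
# exact analytic rate dQ/dt (mg/day). Three families are exponential
# (first-order, Weibull, biexponential), one is rational (second-order) and
# six are polynomial (zero-order, Korsmeyer-Peppas, Higuchi, Hixson-Crowell,
# Peppas-Sahlin, Population Council). Bounded families approach an asymptote
# (Qmax or Dose); polynomial families grow without bound, which is why they
# are poor candidates for multi-year implants even when they fit well over
# the observed window.
#
# Sign conventions: all rate constants are non-negative. The second-order
# form is the solution of dQ/dt = k2 * (Qmax - Q)^2, i.e.
# Q = Qmax * (1 - 1 / (1 + Qmax * k2 * t)), which is non-negative and free of
# the finite-time singularity the naive (1 - Qmax*k2*t) denominator has.
# Hixson-Crowell's cube-root law is clamped at full depletion
# (t >= Qhc^(1/3)/khc): past that time the cube re-grows unphysically.

.param_units <- c(
  Qmax = "mg", Qb1 = "mg", Qhc = "mg", Dose = "mg",
  k = "mg/day", k1 = "1/day", k2 = "1/(mg day)", kb1 = "1/day",
  kb2 = "1/day", kw = "1/day", khc = "mg^(1/3)/day",
  kkp = "mg/day^n", kps1 = "mg/day^m", kps2 = "mg/day^(2m)",
  kpc1 = "mg/day^(1/2)", kpc2 = "mg/day",
  l = "-", n = "-", m = "-"
)

.families <- list(
  zero_order = list(
    parameters = "k",
    fixed = character(),
    bounded = FALSE,
    q = function(t, p) p[["k"]] * t,
    dq = function(t, p) rep(p[["k"]], length(t)),
    grad = function(t, p, free) cbind(k = t)[, free, drop = FALSE]
  ),
  first_order = list(
    parameters = c("Qmax", "k1"),
    fixed = character(),
    bounded = TRUE,
    q = function(t, p) p[["Qmax"]] * (1 - exp(-p[["k1"]] * t)),
    dq = function(t, p) p[["Qmax"]] * p[["k1"]] * exp(-p[["k1"]] * t),
    grad = function(t, p, free) {
      e <- exp(-p[["k1"]] * t)
      cbind(Qmax = 1 - e, k1 = p[["Qmax"]] * t * e)[, free, drop = FALSE]
    }
  ),
  second_order = list(
    parameters = c("Qmax", "k2"),
    fixed = character(),
    bounded = TRUE,
    q = function(t, p) {
      u <- 1 + p[["Qmax"]] * p[["k2"]] * t
      p[["Qmax"]] * (1 - 1 / u)
    },
    dq = function(t, p) {
      u <- 1 + p[["Qmax"]] * p[["k2"]] * t
      p[["k2"]] * p[["Qmax"]]^2 / u^2
    }
  ),
  higuchi = list(
    parameters = "kH",
    fixed = character(),
    bounded = FALSE,
    q = function(t, p) p[["kH"]] * sqrt(t),
    dq = function(t, p) p[["kH"]] / (2 * sqrt(t)),
    grad = function(t, p, free) cbind(kH = sqrt(t))[, free, drop = FALSE]
  ),
  korsmeyer_peppas = list(
    parameters = c("kkp", "n"),
    fixed = character(),
    bounded = FALSE,
    q = function(t, p) p[["kkp"]] * t^p[["n"]],
    dq = function(t, p) p[["n"]] * p[["kkp"]] * t^(p[["n"]] - 1)
  ),
  hixson_crowell = list(
    parameters = c("Qhc", "khc"),
    fixed = character(),
    bounded = FALSE, # listed range is [0, Inf) but the form is clamped at Qhc
    q = function(t, p) {
      root <- p[["Qhc"]]^(1 / 3)
      td <- root / p[["khc"]]
      out <- p[["Qhc"]] - (root - p[["khc"]] * pmin(t, td))^3
      if (any(t > td)) {
        attr(out, "clamped") <- TRUE
        warn(sprintf(
          "Hixson-Crowell release clamped at Qhc = %g mg for t >= %.4g days (depletion).",
          p[["Qhc"]], td
        ), class = "larkin_depletion_clamp")
      }
      out
    },
    dq = function(t, p) {
      root <- p[["Qhc"]]^(1 / 3)
      td <- root / p[["khc"]]
      ifelse(t >= td, 0, 3 * p[["khc"]] * (root - p[["khc"]] * t)^2)
    }
  ),
  weibull = list(
    parameters = c("Qmax", "kw", "l"),
    fixed = character(),
    bounded = TRUE,
    q = function(t, p) p[["Qmax"]] * (1 - exp(-(p[["kw"]] * t)^p[["l"]])),
    dq = function(t, p) {
      kt <- p[["kw"]] * t
      p[["kw"]] * p[["Qmax"]] * p[["l"]] * kt^(p[["l"]] - 1) * exp(-kt^p[["l"]])
    }
  ),
  biexponential = list(
    parameters = c("Dose", "Qb1", "kb1", "kb2"),
    fixed = "Dose",
    bounded = TRUE,
    q = function(t, p) {
      p[["Dose"]] - p[["Qb1"]] * exp(-p[["kb1"]] * t) -
        (p[["Dose"]] - p[["Qb1"]]) * exp(-p[["kb2"]] * t)
    },
    # exact derivative of the cumulative form above
    dq = function(t, p) {
      p[["kb1"]] * p[["Qb1"]] * exp(-p[["kb1"]] * t) +
        p[["kb2"]] * (p[["Dose"]] - p[["Qb1"]]) * exp(-p[["kb2"]] * t)
    },
    grad = function(t, p, free) {
      e1 <- exp(-p[["kb1"]] * t)
      e2 <- exp(-p[["kb2"]] * t)
      cbind(
        Dose = 1 - e2,
        Qb1 = e2 - e1,
        kb1 = p[["Qb1"]] * t * e1,
        kb2 = (p[["Dose"]] - p[["Qb1"]]) * t * e2
      )[, free, drop = FALSE]
    }
  ),
  peppas_sahlin = list(
    parameters = c("kps1", "kps2", "m"),
    fixed = character(),
    bounded = FALSE,
    q = function(t, p) p[["kps1"]] * t^p[["m"]] + p[["kps2"]] * t^(2 * p[["m"]]),
    dq = function(t, p) {
      m <- p[["m"]]
      m * p[["kps1"]] * t^(m - 1) + 2 * m * p[["kps2"]] * t^(2 * m - 1)
    }
  ),
  population_council = list(
    parameters = c("kpc1", "kpc2"),
    fixed = character(),
    bounded = FALSE,
    q = function(t, p) p[["kpc1"]] * sqrt(t) + p[["kpc2"]] * t,
    dq = function(t, p) p[["kpc1"]] / (2 * sqrt(t)) + p[["kpc2"]],
    grad = function(t, p, free) {
      cbind(kpc1 = sqrt(t), kpc2 = t)[, free, drop = FALSE]
    }
  )
)

#' List the available release-model families
#'
#' @return A tibble with one row per family: its id, parameter names, number
#'   of free parameters, and whether the cumulative release is bounded by an
#'   asymptote (relevant for multi-year implants, where unbounded polynomial
#'   families eventually exceed the loaded dose).
#' @examples
#' release_families()
#' @export
release_families <- function() {
  tibble::tibble(
    family_id = names(.families),
    parameters = purrr::map(.families, "parameters"),
    n_free = purrr::map_int(
      .families,
      ~ length(setdiff(.x$parameters, .x$fixed))
    ),
    bounded = purrr::map_lgl(.families, "bounded")
  )
}

family_def <- function(family) {
  if (!is.character(family) || length(family) != 1L || !family %in% names(.families)) {
    abort(sprintf(
      "Unknown model family %s. Available: %s.",
      deparse(family), paste(names(.families), collapse = ", ")
    ))
  }
  .families[[family]]
}

free_parameters <- function(family) {
  def <- family_def(family)
  setdiff(def$parameters, def$fixed)
}

# Validate a named parameter list/vector for a family. Amount-like
# parameters must be non-negative, exponents strictly positive, rate
# constants non-negative; the biexponential fast phase cannot exceed Dose.
validate_params <- function(family, params) {
  def <- family_def(family)
  params <- as.list(params)
  missing <- setdiff(def$parameters, names(params))
  if (length(missing) > 0) {
    abort(sprintf(
      "Family '%s' needs parameter(s): %s.", family,
      paste(missing, collapse = ", ")
    ))
  }
  vals <- unlist(params[def$parameters])
  if (!all(is.finite(vals))) abort("All parameters must be finite numbers.")
  amounts <- intersect(names(vals), c("Qmax", "Qb1", "Qhc", "Dose"))
  if (any(vals[amounts] < 0)) abort("Amount parameters must be >= 0 mg.")
  expo <- intersect(names(vals), c("l", "n", "m"))
  if (any(vals[expo] <= 0)) abort("Exponents must be > 0.")
  rates <- setdiff(names(vals), c(amounts, expo))
  if (any(vals[rates] < 0)) abort("Rate constants must be >= 0.")
  if (family == "biexponential" && vals[["Qb1"]] > vals[["Dose"]]) {
    abort("Biexponential fast phase Qb1 cannot exceed Dose.")
  }
  as.list(vals)
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite numeric days.")
  if (any(t < 0)) abort("Times must be >= 0 days.")
  invisible(t)
}

#' Cumulative released amount Q(t)
#'
#' Evaluates the closed-form cumulative release of a model family at times
#' `t` (days since insertion).
#'
#' @param t Times in days, `>= 0`. Vectorized.
#' @param family Family id; see [release_families()].
#' @param params Named list or vector of parameters for the family (mg for
#'   amounts, day^-1-scale rate constants, dimensionless exponents).
#' @return Numeric vector of released amounts in mg. For Hixson-Crowell the
#'   value is clamped at `Qhc` past the depletion time `Qhc^(1/3)/khc`, with
#'   a warning of class `larkin_depletion_clamp`.
#' @examples
#' release_amount(365, "first_order", list(Qmax = 67.86, k1 = 9e-4))
#' @export
release_amount <- function(t, family, params) {
  check_times(t)
  def <- family_def(family)
  p <- validate_params(family, params)
  q <- def$q(t, p)
  attr_clamped <- attr(q, "clamped")
  q <- as.numeric(q)
  if (isTRUE(attr_clamped)) attr(q, "clamped") <- TRUE
  q
}

#' Instantaneous release rate dQ/dt
#'
#' Analytic derivative of [release_amount()], in mg/day. Families with a
#' square-root or sub-linear power term (Higuchi, Korsmeyer-Peppas with
#' n < 1, Peppas-Sahlin, Population Council) have an infinite rate at t = 0;
#' the singularity is the model's, not an error.
#'
#' @inheritParams release_amount
#' @return Numeric vector of release rates in mg/day (0 past the
#'   Hixson-Crowell depletion time).
#' @examples
#' release_rate(0, "first_order", list(Qmax = 67.86, k1 = 9e-4)) # Qmax * k1
#' @export
release_rate <- function(t, family, params) {
  check_times(t)
  def <- family_def(family)
  p <- validate_params(family, params)
  as.numeric(def$dq(t, p))
}

# Gradient of Q(t) with respect to the named free parameters; analytic where
# the registry provides one, central finite differences otherwise.
# Returns a length(t) x length(free) matrix.
param_gradient <- function(t, family, params, free = free_parameters(family)) {
  def <- family_def(family)
  p <- validate_params(family, params)
  if (!is.null(def$grad)) {
    g <- def$grad(t, p, free)
    return(g)
  }
  g <- matrix(0, length(t), length(free), dimnames = list(NULL, free))
  for (nm in free) {
    h <- max(abs(p[[nm]]), 1e-4) * 1e-6
    up <- p
    dn <- p
    up[[nm]] <- p[[nm]] + h
    dn[[nm]] <- max(p[[nm]] - h, 0)
    hh <- up[[nm]] - dn[[nm]]
    g[, nm] <- (suppressWarnings(def$q(t, up)) - suppressWarnings(def$q(t, dn))) / hh
  }
  g
}

#' Reduce a family to its special case
#'
#' Several families contain simpler families at particular exponent values:
#' Weibull with `l = 1` is first-order, Korsmeyer-Peppas with `n = 1` is
#' zero-order and with `n = 0.5` is Higuchi, Peppas-Sahlin with `m = 0.5` is
#' Population Council. When the relevant exponent equals its special-case
#' value (within `tol`), the reduced family and remapped parameters are
#' returned; otherwise the input is returned unchanged. The reduction always
#' preserves the curve Q(t) exactly.
#'
#' @inheritParams release_amount
#' @param tol Absolute tolerance on the exponent match; default `1e-12`.
#' @return A list with elements `family` and `params`.
#' @examples
#' reduce_special_case("weibull", list(Qmax = 67.86, kw = 9e-4, l = 1))
#' @export
reduce_special_case <- function(family, params, tol = 1e-12) {
  p <- validate_params(family, params)
  near <- function(a, b) abs(a - b) <= tol
  if (family == "weibull" && near(p$l, 1)) {
    return(list(family = "first_order", params = list(Qmax = p$Qmax, k1 = p$kw)))
  }
  if (family == "korsmeyer_peppas" && near(p$n, 1)) {
    return(list(family = "zero_order", params = list(k = p$kkp)))
  }
  if (family == "korsmeyer_peppas" && near(p$n, 0.5)) {
    return(list(family = "higuchi", params = list(kH = p$kkp)))
  }
  if (family == "peppas_sahlin" && near(p$m, 0.5)) {
    return(list(
      family = "population_council",
      params = list(kpc1 = p$kps1, kpc2 = p$kps2)
    ))
  }
  list(family = family, params = p)
}

#' Serialize model parameters to and from JSON
#'
#' Round-trip-stable JSON representation of a parameterized family:
#' `{"family_id": ..., "parameters": {...}, "units": {...}}` with parameters
#' in the family's canonical order.
#'
#' @inheritParams release_amount
#' @param json A JSON string produced by `params_to_json()`.
#' @return `params_to_json()` returns a JSON string; `params_from_json()`
#'   returns a list with `family` and `params`.
#' @examples
#' json <- params_to_json("first_order", list(k1 = 9e-4, Qmax = 67.86))
#' params_from_json(json)$params
#' @export
params_to_json <- function(family, params) {
  def <- family_def(family)
  p <- validate_params(family, params)
  ord <- def$parameters
  jsonlite::toJSON(
    list(
      family_id = family,
      parameters = p[ord],
      units = as.list(.param_units[ord])
    ),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname params_to_json
#' @export
params_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  params <- validate_params(doc$family_id, doc$parameters)
  list(family = doc$family_id, params = params)
}
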