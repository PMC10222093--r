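#' Population simulation configuration
#'
#' Inter-individual variability (IIV) is modeled as independent,
#' median-preserving lognormal multiplicative deviates on selected
#' parameters: a subject's value is `typical * exp(sdlog * z)` with
#' `sdlog = sqrt(log(1 + CV^2))` and `z ~ N(0, 1)`, so the population
#' median equals the typical value (no `-sdlog^2/2` mean shift). No
#' parameter correlations are imposed.
#'
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param iiv Named non-negative CVs (fractions), e.g.
#'   `c(k1 = 0.3, CL = 0.3)`. Names must be release parameters of the
#'   chosen input family or disposition parameters (`ka`, `CL`, `V`).
#' @param seed Integer seed; the same seed reproduces the simulation
#'   bitwise.
#' @param percentiles Probabilities for the reported bands.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_subjects = 100L, iiv = c(CL = 0.3),
                              seed = 1L, percentiles = c(0.025, 0.5, 0.975)) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (length(iiv) > 0 && (is.null(names(iiv)) || any(!nzchar(names(iiv))))) {
    abort("`iiv` must be a named vector of CVs.")
  }
  if (any(iiv < 0)) abort("CVs must be >= 0.")
  stopifnot(all(percentiles > 0 & percentiles < 1))
  structure(
    list(
      n_subjects = as.integer(n_subjects), iiv = iiv,
      seed = as.integer(seed), percentiles = sort(percentiles)
    ),
    class = "population_config"
  )
}

#' Simulate a population of concentration profiles
#'
#' Draws per-subject parameter deviates per [population_config()], runs
#' [simulate_concentration()] for each subject, and summarizes per-time
#' mean and percentile bands. With all CVs zero every band coincides with
#' the typical-value profile. Identical seeds give identical output.
#'
#' @inheritParams simulate_concentration
#' @param config A [population_config()].
#' @return A list of class `population_simulation` with elements `bands`
#'   (tibble: `time_days`, `mean`, one `p<percentile>` column per requested
#'   percentile), `typical` (the typical-value profile), `n_subjects` and
#'   `config`.
#' @export
simulate_population <- function(implant, family, params, disposition, config,
                                times = seq(0, 1825, by = 1),
                                rescale_qb1 = FALSE) {
  stopifnot(inherits(config, "population_config"))
  check_implant(implant)
  params <- as.list(params)
  disp <- unclass(disposition)
  iiv <- config$iiv
  known <- c(names(params), "ka", "CL", "V")
  bad <- setdiff(names(iiv), known)
  if (length(bad) > 0) {
    abort(sprintf(
      "IIV name(s) not among model parameters: %s.",
      paste(bad, collapse = ", ")
    ))
  }
  active <- names(iiv)[iiv > 0]
  n <- config$n_subjects
  z <- withr::with_seed(
    config$seed,
    matrix(rnorm(n * length(active)), nrow = n,
           dimnames = list(NULL, active))
  )
  conc <- matrix(NA_real_, nrow = length(times), ncol = n)
  for (i in seq_len(n)) {
    p_i <- params
    d_i <- disp
    for (nm in active) {
      sdlog <- sqrt(log(1 + iiv[[nm]]^2))
      fac <- exp(sdlog * z[i, nm])
      if (nm %in% names(p_i)) p_i[[nm]] <- p_i[[nm]] * fac else d_i[[nm]] <- d_i[[nm]] * fac
    }
    prof <- simulate_concentration(
      implant, family, p_i,
      disposition_params(ka = d_i$ka, CL = d_i$CL, V = d_i$V, F = d_i$F),
      times = times, rescale_qb1 = rescale_qb1
    )
    conc[, i] <- prof$conc_pg_ml
  }
  qs <- t(apply(conc, 1, quantile, probs = config$percentiles, names = FALSE))
  bands <- tibble::tibble(
    time_days = times,
    mean = rowMeans(conc)
  )
  for (j in seq_along(config$percentiles)) {
    bands[[paste0("p", 100 * config$percentiles[j])]] <- qs[, j]
  }
  typical <- simulate_concentration(
    implant, family, params, disposition,
    times = times, rescale_qb1 = rescale_qb1
  )
  structure(
    list(
      bands = bands, typical = typical,
      n_subjects = n, config = config
    ),
    class = "population_simulation"
  )
}

#' @export
print.population_simulation <- function(x, ...) {
  cat(sprintf(
    "<population_simulation> %d subjects, %d time points, seed %d\n",
    x$n_subjects, nrow(x$bands), x$config$seed
  ))
  print(head(x$bands, 5))
  invisible(x)
}
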