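#' Plot a release-model fit
#'
#' Observed amounts (with SE bars when present), the fitted cumulative
#' release curve, and the delta-method prediction band.
#'
#' @param object A `release_fit`.
#' @param level Band level; default from the fit.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot release_fit
#' @export
autoplot.release_fit <- function(object, level = NULL, n_grid = 200, ...) {
  amt <- object$data[object$data$type == "amount", ]
  t_max <- max(object$data$time_days)
  grid <- seq(0, t_max, length.out = n_grid)
  band <- prediction_band(object, grid, level = level)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$time_days)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_pointrange(
      data = amt,
      ggplot2::aes(
        y = .data$value,
        ymin = .data$value - ifelse(is.na(.data$se), 0, .data$se),
        ymax = .data$value + ifelse(is.na(.data$se), 0, .data$se)
      ),
      colour = "firebrick", size = 0.3
    ) +
    ggplot2::labs(
      x = "Time since insertion (days)",
      y = "Cumulative released amount (mg)",
      title = sprintf("%s fit (adjusted R² = %.4f)", object$family, object$adjusted_r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated concentration profile
#'
#' @param object A `concentration_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concentration_profile
#' @export
autoplot.concentration_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_days, y = .data$conc_pg_ml)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time since insertion (days)",
      y = "Plasma concentration (pg/mL)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot population percentile bands
#'
#' Mean profile with the outermost requested percentile band.
#'
#' @param object A `population_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_simulation
#' @export
autoplot.population_simulation <- function(object, ...) {
  b <- object$bands
  pcols <- grep("^p", names(b), value = TRUE)
  lo <- pcols[1]
  hi <- pcols[length(pcols)]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$time_days)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(
      x = "Time since insertion (days)",
      y = "Plasma concentration (pg/mL)",
      title = sprintf("Population simulation (n = %d)", object$n_subjects)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a model ranking
#'
#' @param ranking Output of [compare_models()].
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(ranking) {
  stopifnot(all(c("family_id", "adjusted_r2") %in% names(ranking)))
  ggplot2::ggplot(
    ranking,
    ggplot2::aes(
      x = stats::reorder(.data$family_id, .data$adjusted_r2),
      y = .data$adjusted_r2
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Adjusted R²") +
    ggplot2::theme_minimal()
}
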