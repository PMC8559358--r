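#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an individual-level fit
#'
#' One row per core parameter (7 coefficients plus the two process
#' scales): posterior mean, sd, 90\% equal-tailed interval and R-hat.
#'
#' @param x A `persistence_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`.
#' @export
tidy.persistence_fit <- function(x, level = 0.90, ...) {
  d <- pooled_draws(x)
  a <- (1 - level) / 2
  tibble::tibble(
    term = colnames(d),
    estimate = colMeans(d),
    std.error = apply(d, 2, sd),
    conf.low = apply(d, 2, quantile, probs = a),
    conf.high = apply(d, 2, quantile, probs = 1 - a),
    rhat = x$rhat$rhat[match(colnames(d), x$rhat$parameter)]
  )
}

#' @rdname tidy.persistence_fit
#' @export
glance.persistence_fit <- function(x, ...) {
  tibble::tibble(
    individual_id = x$individual_id,
    n_fixes = nrow(x$track),
    n_chains = dim(x$draws)[2],
    n_draws = dim(x$draws)[1] * dim(x$draws)[2],
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    converged = max(x$rhat$rhat, na.rm = TRUE) < 1.01
  )
}

#' Tidy a population-level fit
#'
#' One row per covariate: posterior mean, sd and 90\% credible interval
#' of the population coefficient `beta_p`, plus the posterior mean of
#' the between-individual sd `sigma_beta`.
#'
#' @param x A `population_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble with `year`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `sigma_beta`.
#' @export
tidy.population_fit <- function(x, level = 0.90, ...) {
  a <- (1 - level) / 2
  tibble::tibble(
    year = x$year,
    term = colnames(x$beta_p),
    estimate = colMeans(x$beta_p),
    std.error = apply(x$beta_p, 2, sd),
    conf.low = apply(x$beta_p, 2, quantile, probs = a),
    conf.high = apply(x$beta_p, 2, quantile, probs = 1 - a),
    sigma_beta = colMeans(x$sigma_beta)
  )
}

#' @rdname tidy.population_fit
#' @export
glance.population_fit <- function(x, ...) {
  tibble::tibble(
    year = x$year,
    n_individuals = length(x$individuals),
    n_draws = nrow(x$beta_p),
    mean_acceptance = mean(x$acceptance)
  )
}

#' Plot the estimated persistence series of one individual
#'
#' Posterior mean and 90\% ribbon of `gamma_i` over the season -- the
#' per-individual view of migratory pacing (high values: directional
#' migratory movement; low: encamped). Simulation truth is overlaid when
#' present.
#'
#' @param object A `persistence_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.persistence_fit <- function(object, ...) {
  g <- posterior_gamma(object)
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$timestamp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$gamma_lo,
                                      ymax = .data$gamma_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gamma_mean),
                       color = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = expression(hat(gamma)[i]),
                  title = object$individual_id)
  if ("gamma_true" %in% names(g)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$gamma_true),
                                color = "grey30", linetype = 2)
  }
  p + ggplot2::theme_minimal()
}

#' Coefficient-and-interval plot for population fits
#'
#' Point estimates and 90\% credible intervals per covariate (and per
#' year when several fits are supplied) -- the annual coefficient view
#' of which environmental cues drive migratory movement.
#'
#' @param object A `population_fit` or a list of them.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.population_fit <- function(object, ...) {
  tab <- tidy.population_fit(object)
  plot_population_coefficients(tab)
}

#' @rdname autoplot.population_fit
#' @param table A tidy coefficient table (columns `year`, `term`,
#'   `estimate`, `conf.low`, `conf.high`).
#' @export
plot_population_coefficients <- function(table) {
  tab <- dplyr::filter(table, .data$term != "intercept")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    (if (length(unique(tab$year)) > 1)
      ggplot2::facet_wrap(~year) else NULL) +
    ggplot2::labs(x = "population-level coefficient (logit scale)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot temperature-response curves
#'
#' Per-draw posterior realizations (grey) and posterior-mean curve (red)
#' of persistence versus temperature, faceted by snow depth.
#'
#' @param curves Output of [temperature_response_curves()].
#' @return A ggplot.
#' @export
plot_temperature_response <- function(curves) {
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = dplyr::filter(curves, .data$draw > 0),
      ggplot2::aes(x = .data$temp_c, y = .data$gamma,
                   group = .data$draw),
      color = "grey60", alpha = 0.2) +
    ggplot2::geom_line(
      data = dplyr::filter(curves, .data$draw == 0),
      ggplot2::aes(x = .data$temp_c, y = .data$gamma),
      color = "red", linewidth = 1) +
    ggplot2::facet_wrap(~snow_cm,
                        labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "temperature (degC)",
                  y = expression(hat(gamma))) +
    ggplot2::theme_minimal()
}

#' Plot a predicted persistence surface
#'
#' @param surface Output of [predict_gamma_surface()] (the `draw == 0`
#'   layer is shown).
#' @return A ggplot raster map of expected persistence.
#' @export
plot_gamma_surface <- function(surface) {
  ggplot2::ggplot(dplyr::filter(surface, .data$draw == 0),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  fill = expression(hat(gamma))) +
    ggplot2::theme_minimal()
}
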