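#' Specification for synthetic seasonal covariate fields
#'
#' Describes a regular planar grid and the stochastic seasonal generators
#' for the five environmental covariates used by the persistence model:
#' air temperature (linear seasonal decline plus AR(1) noise), snow depth
#' (zero before a fixed onset day, then non-negative reflected random-walk
#' accumulation), wind speed (AR(1) around a positive mean, floored at 0),
#' NDVI (logistic decline from a summer plateau, 16-day composites) and
#' barometric pressure (AR(1) around a mean). Each variable additionally
#' carries a smooth south-to-north spatial gradient.
#'
#' Defaults emulate an Arctic autumn (mid-August through December):
#' temperatures fall from about 10 degC to deep winter cold, snow begins
#' accumulating in late September and reaches tens of cm by December, and
#' NDVI senesces toward zero.
#'
#' @param nx,ny Number of grid cells in x and y (must be >= 2).
#' @param cell_km Cell-center spacing in km.
#' @param season_start,season_end Season window (UTC); weather fields are
#'   produced every `step_h` hours across it.
#' @param step_h Weather time step in hours; must be 3.
#' @param temp_start_c Mean temperature at season start (degC).
#' @param temp_slope_c_per_day Linear seasonal trend (degC/day).
#' @param temp_ar_sd,temp_ar_phi Innovation sd (degC) and lag-1
#'   autocorrelation of the AR(1) temperature noise.
#' @param temp_gradient_c_per_km Additive north-south gradient
#'   (degC per km of northing; negative means colder to the north).
#' @param snow_onset_day Day of season (0 = season start) before which snow
#'   is exactly zero.
#' @param snow_drift_m,snow_sd_m Mean and sd of the per-step (3-h) snow
#'   depth increment (m); accumulation is reflected to stay non-negative.
#' @param snow_gradient_per_km Multiplicative north-south modulation of
#'   snow depth (fraction per km).
#' @param wind_mean_ms,wind_ar_sd,wind_ar_phi AR(1) wind-speed parameters
#'   (m/s); values are floored at zero.
#' @param ndvi_plateau Summer NDVI plateau in (0, 1].
#' @param ndvi_mid_day,ndvi_scale_days Midpoint (day of season) and time
#'   scale of the logistic NDVI decline.
#' @param ndvi_gradient_per_km Multiplicative north-south NDVI modulation.
#' @param pressure_mean_pa,pressure_ar_sd,pressure_ar_phi AR(1) pressure
#'   parameters (Pa).
#' @param seed Integer seed; field generation is a pure function of
#'   (spec, seed).
#'
#' @return A list of class `covariate_field_spec`.
#' @export
sim_covariate_spec <- function(nx = 30, ny = 30, cell_km = 40,
                               season_start = "2010-08-15 00:00:00",
                               season_end = "2010-12-31 23:59:59",
                               step_h = 3,
                               temp_start_c = 10,
                               temp_slope_c_per_day = -0.25,
                               temp_ar_sd = 3, temp_ar_phi = 0.9,
                               temp_gradient_c_per_km = -0.008,
                               snow_onset_day = 45,
                               snow_drift_m = 0.0006,
                               snow_sd_m = 0.002,
                               snow_gradient_per_km = 3e-4,
                               wind_mean_ms = 4, wind_ar_sd = 1.2,
                               wind_ar_phi = 0.7,
                               ndvi_plateau = 0.8,
                               ndvi_mid_day = 35, ndvi_scale_days = 8,
                               ndvi_gradient_per_km = -2e-4,
                               pressure_mean_pa = 101325,
                               pressure_ar_sd = 250,
                               pressure_ar_phi = 0.9,
                               seed = 1L) {
  spec <- as.list(environment())
  spec$season_start <- as_utc(season_start)
  spec$season_end <- as_utc(season_end)
  class(spec) <- "covariate_field_spec"
  spec
}

# stationary-start AR(1) series of length n
ar1_series <- function(n, phi, sd_innov) {
  if (sd_innov <= 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_innov / sqrt(max(1 - phi^2, 1e-12)))
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + rnorm(1, 0, sd_innov)
  x
}

#' Generate synthetic covariate fields
#'
#' Realizes the stochastic generators described by a
#' [sim_covariate_spec()] on its grid and time axes. Weather variables are
#' produced at 3-h cadence; NDVI as 16-day composites. Invariants enforced
#' by construction: snow is exactly 0 strictly before the onset day and
#' non-negative everywhere; NDVI lies in \[0, 1\]; wind is non-negative.
#'
#' @param spec A [sim_covariate_spec()].
#' @return Named list of [covariate_stack()] objects (`temperature`,
#'   `snow`, `wind`, `ndvi`, `pressure`).
#' @export
generate_covariate_fields <- function(spec) {
  stopifnot(inherits(spec, "covariate_field_spec"))
  if (spec$nx < 2 || spec$ny < 2) stop("grid dimensions must be >= 2")
  if (spec$step_h != 3) stop("weather time step must be 3 h")
  if (spec$season_end <= spec$season_start) stop("empty time range")

  with_seed_if(spec$seed, {
    x <- spec$cell_km * (seq_len(spec$nx) - 0.5)
    y <- spec$cell_km * (seq_len(spec$ny) - 0.5)
    ymid <- mean(range(y))
    times <- seq(spec$season_start, spec$season_end, by = 3 * 3600)
    nt <- length(times)
    day <- as.numeric(times - spec$season_start, units = "days")

    north <- y - ymid  # km north of grid middle

    # temperature: linear decline + AR(1), additive N-S gradient
    temp_base <- spec$temp_start_c + spec$temp_slope_c_per_day * day +
      ar1_series(nt, spec$temp_ar_phi, spec$temp_ar_sd)
    temp <- outer(temp_base, spec$temp_gradient_c_per_km * north, `+`)

    # snow: zero before onset, reflected random-walk accumulation after;
    # multiplicative gradient keeps pre-onset zeros exact
    acc <- numeric(nt)
    post <- which(day >= spec$snow_onset_day)
    s <- 0
    for (t in post) {
      s <- abs(s + rnorm(1, spec$snow_drift_m, spec$snow_sd_m))
      acc[t] <- s
    }
    snow_mod <- pmax(1 + spec$snow_gradient_per_km * north, 0)
    snow <- outer(acc, snow_mod, `*`)

    # wind: AR(1) around positive mean, small N-S gradient, floored at 0
    wind_base <- spec$wind_mean_ms +
      ar1_series(nt, spec$wind_ar_phi, spec$wind_ar_sd)
    wind <- pmax(outer(wind_base, 5e-4 * north, `+`), 0)

    # pressure: AR(1) around mean
    pres_base <- spec$pressure_mean_pa +
      ar1_series(nt, spec$pressure_ar_phi, spec$pressure_ar_sd)
    pres <- outer(pres_base, -0.5 * north, `+`)

    # NDVI: logistic decline, 16-day composites, clamped to [0, 1]
    ndvi_times <- seq(spec$season_start, spec$season_end, by = 16 * 86400)
    ndvi_day <- as.numeric(ndvi_times - spec$season_start, units = "days") + 8
    ndvi_base <- spec$ndvi_plateau /
      (1 + exp((ndvi_day - spec$ndvi_mid_day) / spec$ndvi_scale_days))
    ndvi_mod <- pmax(1 + spec$ndvi_gradient_per_km * north, 0)
    ndvi <- pmin(pmax(outer(ndvi_base, ndvi_mod, `*`), 0), 1)

    expand_x <- function(m) {
      # replicate a (time x y) matrix across x cells -> array (time, y, x)
      array(rep(as.vector(m), spec$nx), dim = c(nrow(m), ncol(m), spec$nx))
    }
    list(
      temperature = covariate_stack("temperature", x, y, times,
                                    expand_x(temp), "degC"),
      snow = covariate_stack("snow", x, y, times, expand_x(snow), "m"),
      wind = covariate_stack("wind", x, y, times, expand_x(wind), "m s-1"),
      ndvi = covariate_stack("ndvi", x, y, ndvi_times, expand_x(ndvi), "1",
                             time_rule = "constant"),
      pressure = covariate_stack("pressure", x, y, times, expand_x(pres),
                                 "Pa")
    )
  })
}

#' Field climatology used as a fixed standardization reference
#'
#' Means and standard deviations of each raw covariate over the full
#' space-time extent of the supplied stacks. Useful as a fixed
#' standardization table shared between simulation and fitting.
#'
#' @param stacks Named list of [covariate_stack()] objects.
#' @return A tibble with columns `variable`, `mean`, `sd`.
#' @export
field_scaling <- function(stacks) {
  purrr::map_dfr(stacks[mp_variables()], function(s) {
    tibble::tibble(variable = s$variable,
                   mean = mean(s$values), sd = stats::sd(as.vector(s$values)))
  })
}
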