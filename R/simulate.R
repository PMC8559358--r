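#' Draw individual-level coefficients from the population model
#'
#' Each individual's coefficient vector is drawn independently per term as
#' `beta[j, k] ~ Normal(beta_p[k], sigma_beta[k]^2)`, the population
#' hierarchy linking individuals to annual population-level effects.
#'
#' @param beta_p Numeric vector of 7 population-level coefficients on the
#'   logit scale, ordered as [mp_terms()].
#' @param sigma_beta Numeric vector of 7 non-negative between-individual
#'   standard deviations.
#' @param n_individuals Number of individuals to draw (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble with `individual_id` and one column per term.
#' @export
draw_individual_coefficients <- function(beta_p, sigma_beta, n_individuals,
                                         seed = NULL) {
  stopifnot(length(beta_p) == 7, length(sigma_beta) == 7,
            n_individuals >= 1)
  if (any(sigma_beta < 0)) stop("sigma_beta must be non-negative")
  with_seed_if(seed, {
    draws <- vapply(seq_len(7), function(k) {
      rnorm(n_individuals, beta_p[k], sigma_beta[k])
    }, numeric(n_individuals))
    draws <- matrix(draws, nrow = n_individuals)
    colnames(draws) <- mp_terms()
    dplyr::bind_cols(
      tibble::tibble(individual_id = sprintf("sim%02d",
                                             seq_len(n_individuals))),
      tibble::as_tibble(draws)
    )
  })
}

# standardized design row(s) at given locations/times from raw stacks;
# applies the NDVI-under-snow zeroing before standardization
design_at <- function(stacks, x, y, time, scaling, context = NULL) {
  raw <- purrr::map(stacks[mp_variables()], extract_covariate,
                    x = x, y = y, time = time, context = context)
  raw$ndvi[raw$snow > 0] <- 0
  std <- purrr::imap(raw, function(v, nm) {
    row <- scaling[scaling$variable == nm, ]
    (v - row$mean) / row$sd
  })
  cbind(intercept = 1, temperature = std$temperature, snow = std$snow,
        temperature_snow = std$temperature * std$snow,
        wind = std$wind, ndvi = std$ndvi, pressure = std$pressure)
}

#' Simulate a movement track from the generative model
#'
#' Simulates a correlated random walk with dynamic persistence forward in
#' time. At each step i >= 3, the latent logit-persistence is drawn as
#' `eta_i ~ Normal(Z' beta, (dt_i * sigma_nu)^2)` with the covariate
#' vector `Z` evaluated at the previous location (the fields are smooth,
#' so this forward-simulation approximation is benign), and the location
#' as `x_i ~ Normal(x_{i-1} + gamma_i (dt_i/dt_{i-1})(x_{i-1} - x_{i-2}),
#' dt_i * sigma_x^2 * I)` with `gamma_i = plogis(eta_i)`.
#'
#' The first fix is placed at `start`; the second is offset by one
#' diffusive step `Normal(0, dt * sigma_x^2 * I)`; the process equation
#' applies from the third fix onward.
#'
#' @param beta Length-7 coefficient vector (order [mp_terms()]).
#' @param sigma_x Process scale in km per sqrt(hour); > 0.
#' @param sigma_nu Latent scale (logit units per hour); >= 0.
#' @param stacks Named list of [covariate_stack()]s covering the track.
#' @param start Length-2 numeric start location (km).
#' @param n_fixes Number of fixes (>= 3).
#' @param interval_h Fix interval in hours.
#' @param start_time First fix timestamp; defaults to the weather stack's
#'   first slice.
#' @param scaling Standardization table (`variable`, `mean`, `sd`);
#'   defaults to [field_scaling()] of the stacks.
#' @param individual_id Identifier stored in the output.
#' @param seed Optional integer seed.
#' @return A tibble with columns `individual_id`, `timestamp`, `x_km`,
#'   `y_km`, `gamma_true`, `eta_true` (the latter two `NA` for the first
#'   two fixes). The scaling table used is attached as attribute
#'   `"covariate_scaling"`.
#' @export
simulate_track <- function(beta, sigma_x, sigma_nu, stacks, start,
                           n_fixes, interval_h = 8, start_time = NULL,
                           scaling = NULL, individual_id = "sim01",
                           seed = NULL) {
  stopifnot(length(beta) == 7, length(start) == 2, n_fixes >= 3,
            interval_h > 0)
  if (sigma_x <= 0) stop("sigma_x must be positive")
  if (sigma_nu < 0) stop("sigma_nu must be non-negative")
  if (is.null(start_time)) start_time <- stacks$temperature$time[1]
  start_time <- as_utc(start_time)
  if (is.null(scaling)) scaling <- field_scaling(stacks)

  with_seed_if(seed, {
    times <- start_time + (seq_len(n_fixes) - 1) * interval_h * 3600
    xy <- matrix(NA_real_, n_fixes, 2)
    eta <- rep(NA_real_, n_fixes)
    xr <- range(stacks$temperature$x); yr <- range(stacks$temperature$y)
    inside <- function(p) p[1] >= xr[1] && p[1] <= xr[2] &&
      p[2] >= yr[1] && p[2] <= yr[2]
    if (!inside(start)) stop("start location lies outside the covariate grid")
    xy[1, ] <- start
    xy[2, ] <- start + rnorm(2, 0, sqrt(interval_h) * sigma_x)
    if (!inside(xy[2, ])) {
      stop(sprintf(
        "simulated track left the covariate grid at step 2 (%.1f, %.1f); enlarge the grid or shorten the track",
        xy[2, 1], xy[2, 2]))
    }
    dt <- rep(interval_h, n_fixes)  # hours since previous fix
    for (i in 3:n_fixes) {
      z <- design_at(stacks, xy[i - 1, 1], xy[i - 1, 2], times[i], scaling,
                     context = sprintf("step %d", i))
      eta[i] <- rnorm(1, drop(z %*% beta), dt[i] * sigma_nu)
      g <- inv_logit(eta[i])
      mu <- xy[i - 1, ] + g * (dt[i] / dt[i - 1]) * (xy[i - 1, ] - xy[i - 2, ])
      xy[i, ] <- rnorm(2, mu, sqrt(dt[i]) * sigma_x)
      if (xy[i, 1] < xr[1] || xy[i, 1] > xr[2] ||
          xy[i, 2] < yr[1] || xy[i, 2] > yr[2]) {
        stop(sprintf(
          "simulated track left the covariate grid at step %d (%.1f, %.1f); enlarge the grid or shorten the track",
          i, xy[i, 1], xy[i, 2]))
      }
    }
    out <- tibble::tibble(
      individual_id = individual_id,
      timestamp = times,
      x_km = xy[, 1], y_km = xy[, 2],
      gamma_true = inv_logit(eta),
      eta_true = eta
    )
    attr(out, "covariate_scaling") <- scaling
    out
  })
}

#' Simulate a population of tracks with known truth
#'
#' Draws individual coefficients from the population hierarchy and
#' simulates one track per individual, all on the same covariate fields.
#' Start locations are jittered around the grid center.
#'
#' @param n_individuals Number of individuals.
#' @param beta_p,sigma_beta Population-level means and between-individual
#'   sds (length 7 each).
#' @param sigma_x,sigma_nu Process scales shared across individuals.
#' @param stacks Covariate fields from [generate_covariate_fields()].
#' @param n_fixes,interval_h Track length and fix cadence.
#' @param start_jitter_km sd of the random start-location offset.
#' @param seed Integer seed controlling the whole simulation.
#' @return A list with `tracks` (one tibble, all individuals),
#'   `coefficients` (true per-individual betas), `scaling` and `truth`
#'   (the population-level parameters).
#' @export
simulate_population <- function(n_individuals, beta_p, sigma_beta,
                                sigma_x, sigma_nu, stacks,
                                n_fixes = 300, interval_h = 8,
                                start_jitter_km = 40, seed = 1L) {
  scaling <- field_scaling(stacks)
  center <- c(mean(range(stacks$temperature$x)),
              mean(range(stacks$temperature$y)))
  with_seed_if(seed, {
    coefs <- draw_individual_coefficients(beta_p, sigma_beta,
                                          n_individuals)
    tracks <- purrr::map_dfr(seq_len(n_individuals), function(j) {
      beta_j <- as.numeric(coefs[j, mp_terms()])
      start <- center + rnorm(2, 0, start_jitter_km)
      simulate_track(beta_j, sigma_x, sigma_nu, stacks, start,
                     n_fixes = n_fixes, interval_h = interval_h,
                     scaling = scaling,
                     individual_id = coefs$individual_id[j])
    })
    list(tracks = tracks, coefficients = coefs, scaling = scaling,
         truth = list(beta_p = setNames(beta_p, mp_terms()),
                      sigma_beta = setNames(sigma_beta, mp_terms()),
                      sigma_x = sigma_x, sigma_nu = sigma_nu))
  })
}

#' Default population-level simulation parameters
#'
#' A realistic autumn-migration parameterization used throughout the
#' package's examples and tests: persistence rises as temperatures fall,
#' rises further when snow arrives while temperatures are still mild
#' (positive temperature-by-snow interaction), and responds more weakly
#' to wind, NDVI senescence and pressure. Magnitudes are chosen so that
#' simulated seasons span the full behavioral contrast observed in
#' migratory caribou -- from encamped movement (persistence near 0) to
#' strongly directional migratory runs (persistence near 1); that
#' contrast is also what makes the latent logit-scale coefficients
#' statistically identifiable from 8-h tracks.
#'
#' @return A list with `beta_p`, `sigma_beta`, `sigma_x` (km/sqrt(h)) and
#'   `sigma_nu` (logit units per hour).
#' @export
default_simulation_parameters <- function() {
  list(
    beta_p = setNames(c(1, -1.5, -0.8, 1.5, 0.6, -1, 0.5),
                      mp_terms()),
    sigma_beta = setNames(rep(0.2, 7), mp_terms()),
    sigma_x = 1,
    sigma_nu = 0.1
  )
}
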