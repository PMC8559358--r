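# Shared small fixtures, built once per test run. Kept deliberately tiny:
# a 12 x 12 grid over a short season is enough for interpolation,
# annotation and simulation tests; the acceptance tests build their own
# full-size conditions.

small_spec <- function(seed = 7) {
  sim_covariate_spec(nx = 12, ny = 12, cell_km = 40,
                     season_start = "2010-08-15 00:00:00",
                     season_end = "2010-10-15 23:59:59",
                     seed = seed)
}

small_stacks <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_covariate_fields(small_spec())
    cache
  }
})

# a constant-valued stack for interpolation identities
constant_stack <- function(value = 3.5, variable = "temperature") {
  times <- as.POSIXct("2010-08-15 00:00:00", tz = "UTC") + (0:9) * 3 * 3600
  covariate_stack(variable, x = c(10, 20, 30), y = c(10, 20, 30),
                  time = times,
                  values = array(value, dim = c(10, 3, 3)), units = "u")
}

# minimal regular track tibble
make_track <- function(n = 10, interval_h = 8, start = c(100, 100),
                       id = "a", t0 = "2010-09-27 00:00:00") {
  tibble::tibble(
    individual_id = id,
    timestamp = as.POSIXct(t0, tz = "UTC") + (0:(n - 1)) * interval_h * 3600,
    x_km = start[1] + seq_len(n), y_km = start[2] + seq_len(n) * 0.5
  )
}

# simulate a track directly from the model equations with an explicit
# design matrix -- an independent generative path used as an oracle for
# the fitting tests (does not go through simulate_track)
direct_sim <- function(n, beta, sigma_x, sigma_nu, dt = 8, Z = NULL,
                       seed = 1) {
  withr::with_seed(seed, {
    if (is.null(Z)) Z <- cbind(1, matrix(rnorm(n * 6), n, 6))
    xy <- matrix(0, n, 2)
    xy[2, ] <- rnorm(2, 0, sqrt(dt) * sigma_x)
    eta <- rep(NA_real_, n)
    for (i in 3:n) {
      eta[i] <- rnorm(1, sum(Z[i, ] * beta), dt * sigma_nu)
      g <- plogis(eta[i])
      mu <- xy[i - 1, ] + g * (xy[i - 1, ] - xy[i - 2, ])
      xy[i, ] <- rnorm(2, mu, sqrt(dt) * sigma_x)
    }
    track <- tibble::tibble(
      individual_id = "direct",
      timestamp = as.POSIXct("2010-08-15 00:00:00", tz = "UTC") +
        (0:(n - 1)) * dt * 3600,
      x_km = xy[, 1], y_km = xy[, 2],
      gamma_true = plogis(eta), eta_true = eta
    )
    list(track = track, Z = Z, eta = eta)
  })
}
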