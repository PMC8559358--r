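test_that("generated fields satisfy their structural invariants", {
  stacks <- small_stacks()
  spec <- small_spec()

  # snow exactly zero strictly before onset, non-negative after
  day <- as.numeric(stacks$snow$time - spec$season_start, units = "days")
  pre <- which(day < spec$snow_onset_day)
  expect_true(all(stacks$snow$values[pre, , ] == 0))
  expect_true(all(stacks$snow$values >= 0))

  expect_true(all(stacks$ndvi$values >= 0 & stacks$ndvi$values <= 1))
  expect_true(all(stacks$wind$values >= 0))

  # 3-h cadence for weather, strictly increasing everywhere
  expect_equal(unique(diff(as.numeric(stacks$temperature$time))), 3 * 3600)
  for (s in stacks) expect_true(all(diff(as.numeric(s$time)) > 0))
})

test_that("field generation is a pure function of (spec, seed)", {
  a <- generate_covariate_fields(small_spec(seed = 3))
  b <- generate_covariate_fields(small_spec(seed = 3))
  c <- generate_covariate_fields(small_spec(seed = 4))
  expect_identical(a$temperature$values, b$temperature$values)
  expect_identical(a$snow$values, b$snow$values)
  expect_false(identical(a$temperature$values, c$temperature$values))
})

test_that("invalid field specifications are rejected", {
  expect_error(generate_covariate_fields(sim_covariate_spec(nx = 1)),
               "dimensions")
  expect_error(generate_covariate_fields(sim_covariate_spec(step_h = 6)),
               "3 h")
  expect_error(
    generate_covariate_fields(
      sim_covariate_spec(season_start = "2010-10-01",
                         season_end = "2010-09-01")),
    "empty")
})

test_that("seasonal temperature trend is recovered by OLS on grid means", {
  # generator contract: grid-mean temperature declines at the specified
  # rate; check the fitted slope against the configured -0.3 degC/day
  spec <- sim_covariate_spec(nx = 8, ny = 8,
                             season_start = "2010-08-15 00:00:00",
                             season_end = "2010-11-22 23:59:59",  # ~100 d
                             temp_slope_c_per_day = -0.3,
                             temp_ar_sd = 1, temp_ar_phi = 0.8,
                             seed = 11)
  stacks <- generate_covariate_fields(spec)
  day <- as.numeric(stacks$temperature$time - spec$season_start,
                    units = "days")
  gmean <- apply(stacks$temperature$values, 1, mean)
  slope <- coef(lm(gmean ~ day))[2]
  expect_lt(abs(slope - (-0.3)), 0.05)
})

test_that("individual coefficients follow the population hierarchy", {
  beta_p <- c(-0.5, -0.4, -0.25, 0.45, 0.2, -0.3, 0.2)

  # degenerate hierarchy: zero spread returns beta_p exactly
  d0 <- draw_individual_coefficients(beta_p, rep(0, 7), 5, seed = 1)
  for (k in seq_len(7)) {
    expect_equal(unique(d0[[mp_terms()[k]]]), beta_p[k])
  }

  # Monte-Carlo check of mean and sd at large J (term 2: mean -0.5 was
  # verified against rnorm moments directly)
  bp <- beta_p; bp[2] <- -0.5
  d <- draw_individual_coefficients(bp, rep(0.2, 7), 10000, seed = 2)
  expect_lt(abs(mean(d$temperature) - (-0.5)), 0.01)
  expect_lt(abs(sd(d$temperature) - 0.2), 0.01)

  # determinism and input validation
  expect_identical(draw_individual_coefficients(beta_p, rep(0.1, 7), 3,
                                                seed = 9),
                   draw_individual_coefficients(beta_p, rep(0.1, 7), 3,
                                                seed = 9))
  expect_error(draw_individual_coefficients(beta_p, rep(-1, 7), 3),
               "non-negative")
})

test_that("simulated tracks follow the movement process equations", {
  stacks <- small_stacks()

  # sigma_nu = 0: returned latent series equals Z' beta exactly
  beta <- c(0.5, -0.2, 0, 0.1, 0, 0, 0)
  tr <- simulate_track(beta, sigma_x = 0.5, sigma_nu = 0, stacks,
                       start = c(240, 240), n_fixes = 30, seed = 5)
  sc <- attr(tr, "covariate_scaling")
  Zprev <- movepersist:::design_at(stacks, tr$x_km[2:29], tr$y_km[2:29],
                                   tr$timestamp[3:30], sc)
  expect_equal(tr$eta_true[3:30], drop(Zprev %*% beta), tolerance = 1e-10)

  # near-degenerate noise with strong positive intercept: nearly straight
  # line with constant step vector (persistence ~ 1)
  tr2 <- simulate_track(c(20, 0, 0, 0, 0, 0, 0), sigma_x = 1e-4,
                        sigma_nu = 0, stacks, start = c(240, 240),
                        n_fixes = 12, seed = 6)
  steps <- cbind(diff(tr2$x_km), diff(tr2$y_km))
  ref <- steps[2, ]
  for (i in 3:nrow(steps)) {
    expect_equal(steps[i, ], ref, tolerance = 1e-2)
  }

  # determinism and error cases
  expect_identical(
    simulate_track(beta, 1, 0.05, stacks, c(240, 240), 20, seed = 8),
    simulate_track(beta, 1, 0.05, stacks, c(240, 240), 20, seed = 8))
  expect_error(simulate_track(beta, -1, 0.05, stacks, c(240, 240), 20),
               "sigma_x")
  expect_error(
    simulate_track(c(20, 0, 0, 0, 0, 0, 0), 40, 0, stacks,
                   c(440, 440), 200, seed = 1),
    "left the covariate grid")
  expect_error(
    simulate_track(c(20, 0, 0, 0, 0, 0, 0), 1, 0, stacks,
                   c(5000, 440), 20, seed = 1),
    "start location")
})

test_that("displacement variance scales as dt * sigma_x^2", {
  # gamma pinned at 0 (large negative intercept): displacements are pure
  # diffusion with per-axis variance dt * sigma_x^2; Monte-Carlo vs the
  # process equation at dt = 8 h, sigma_x = 0.7 (full-season time axis so
  # the track fits inside the stack's temporal extent)
  stacks <- generate_covariate_fields(
    sim_covariate_spec(nx = 12, ny = 12, cell_km = 40, seed = 21))
  tr <- simulate_track(c(-30, 0, 0, 0, 0, 0, 0), sigma_x = 0.7,
                       sigma_nu = 0, stacks, start = c(240, 240),
                       n_fixes = 400, interval_h = 8, seed = 12)
  dx <- diff(tr$x_km)[-1]
  dy <- diff(tr$y_km)[-1]
  v <- var(c(dx, dy))
  expect_lt(abs(v - 8 * 0.7^2) / (8 * 0.7^2), 0.10)
})

test_that("covariate stacks round-trip through long format", {
  stacks <- small_stacks()
  long <- stacks_to_long(stacks)
  back <- stacks_from_long(long)
  for (v in names(stacks)) {
    expect_equal(back[[v]]$values, stacks[[v]]$values)
    expect_equal(back[[v]]$x, stacks[[v]]$x)
    expect_equal(as.numeric(back[[v]]$time),
                 as.numeric(stacks[[v]]$time))
  }
})
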