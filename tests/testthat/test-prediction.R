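toy_scaling <- function() {
  tibble::tibble(
    variable = c("temperature", "snow", "wind", "ndvi", "pressure"),
    mean = c(-5, 0.10, 4, 0.3, 101300),
    sd = c(8, 0.08, 1.5, 0.25, 400))
}

test_that("gamma surfaces compose standardization, zeroing and the link", {
  stacks <- small_stacks()
  sc <- field_scaling(stacks)
  t_mid <- stacks$temperature$time[100]

  # zero coefficients -> gamma exactly 0.5 everywhere
  s0 <- predict_gamma_surface(stacks, t_mid, rep(0, 7), sc)
  expect_true(all(s0$gamma == 0.5))
  expect_equal(nrow(s0), 12 * 12)

  # single pixel equals the hand-composed linear predictor
  beta <- c(0.2, -0.5, -0.3, 0.6, 0.1, -0.2, 0.15)
  s1 <- predict_gamma_surface(stacks, t_mid, beta, sc)
  px <- s1[s1$x == stacks$temperature$x[3] &
             s1$y == stacks$temperature$y[4], ]
  raw <- vapply(c("temperature", "snow", "wind", "ndvi", "pressure"),
                function(v) extract_covariate(stacks[[v]], px$x, px$y,
                                              t_mid), numeric(1))
  if (raw["snow"] > 0) raw["ndvi"] <- 0
  std <- (raw - sc$mean[match(names(raw), sc$variable)]) /
    sc$sd[match(names(raw), sc$variable)]
  z <- c(1, std["temperature"], std["snow"],
         std["temperature"] * std["snow"], std["wind"], std["ndvi"],
         std["pressure"])
  expect_equal(px$gamma, plogis(sum(z * beta)), tolerance = 1e-12)
  expect_true(all(s1$gamma > 0 & s1$gamma < 1))
})

test_that("temperature response curves bend with snow as the algebra says", {
  sc <- toy_scaling()
  # negative temperature main effect, positive interaction
  beta <- c(0, -0.6, 0, 0.3, 0, 0, 0)
  cur <- temperature_response_curves(beta, sc, temp_c = seq(-30, 10, 2),
                                     snow_cm = c(0, 11, 46))
  expect_true(all(cur$gamma > 0 & cur$gamma < 1))

  # snow 0 cm: slope beta1 + beta3 * s_std with s_std = -1.25 ->
  # -0.6 - 0.375 < 0: strictly decreasing in temperature
  c0 <- dplyr::filter(cur, snow_cm == 0, draw == 0)
  expect_true(all(diff(c0$gamma) < 0))

  # deep snow 46 cm: s_std = (0.46 - 0.10) / 0.08 = 4.5 ->
  # slope -0.6 + 1.35 > 0: strictly increasing
  c46 <- dplyr::filter(cur, snow_cm == 46, draw == 0)
  expect_true(all(diff(c46$gamma) > 0))

  expect_error(temperature_response_curves(
    beta, dplyr::mutate(sc, sd = replace(sd, variable == "snow", 0))),
    "snow sd")
})

test_that("per-draw curves envelope the posterior-mean curve", {
  withr::with_seed(41, {
    draws <- cbind(rnorm(50, 0, 0.2), rnorm(50, -0.6, 0.1),
                   rnorm(50, -0.2, 0.1), rnorm(50, 0.3, 0.1),
                   matrix(rnorm(150, 0, 0.1), 50, 3))
    cur <- temperature_response_curves(draws, toy_scaling(),
                                       temp_c = seq(-20, 0, 5),
                                       snow_cm = 11)
    mean_curve <- dplyr::filter(cur, draw == 0)
    env <- cur |> dplyr::filter(draw > 0) |>
      dplyr::group_by(temp_c) |>
      dplyr::summarise(lo = min(gamma), hi = max(gamma))
    joined <- dplyr::left_join(mean_curve, env, by = "temp_c")
    expect_true(all(joined$gamma >= joined$lo & joined$gamma <= joined$hi))
  })
})

test_that("snow inversion depth solves beta1 + beta3 s_std = 0 exactly", {
  # forced algebra: -(-0.6)/0.3 = 2 standardized units above the mean
  res <- snow_inversion_depth(c(0, -0.6, 0, 0.3, 0, 0, 0),
                              snow_mean = 10, snow_sd = 8)
  expect_equal(res$depth, 26)

  # beta1 = 0: inversion at the snow mean
  res0 <- snow_inversion_depth(c(0, 0, 0, 0.3, 0, 0, 0),
                               snow_mean = 10, snow_sd = 8)
  expect_equal(res0$depth, 10)

  # degenerate interaction: flagged, not an exception
  resd <- snow_inversion_depth(c(0, -0.6, 0, 0, 0, 0, 0),
                               snow_mean = 10, snow_sd = 8)
  expect_true(is.na(resd$depth))
  expect_equal(resd$summary$frac_no_inversion, 1)

  # equivariance: shifting the snow mean shifts the depth by the same
  shift <- snow_inversion_depth(c(0, -0.6, 0, 0.3, 0, 0, 0),
                                snow_mean = 15, snow_sd = 8)
  expect_equal(shift$depth - res$depth, 5)

  # scaling-table interface reports cm from meter-scale metadata
  sc <- toy_scaling()  # snow mean 0.10 m, sd 0.08 m
  via_sc <- snow_inversion_depth(c(0, -0.6, 0, 0.3, 0, 0, 0),
                                 scaling = sc)
  expect_equal(via_sc$depth, 10 + 8 * 2)
})

test_that("per-draw inversion summaries track the draw distribution", {
  withr::with_seed(42, {
    draws <- cbind(0, rnorm(500, -0.6, 0.05), 0, rnorm(500, 0.3, 0.02),
                   0, 0, 0)
    res <- snow_inversion_depth(draws, snow_mean = 10, snow_sd = 8)
    expect_equal(res$summary$n_draws, 500)
    expect_lt(res$summary$frac_no_inversion, 0.01)
    expect_equal(res$depth, 26, tolerance = 1)
    expect_true(res$summary$lo90 < res$depth &
                  res$depth < res$summary$hi90)
  })
})

test_that("surface prediction commutes with standardization", {
  # computing gamma from raw fields + metadata equals standardizing the
  # annotated values first and applying the linear predictor directly
  stacks <- small_stacks()
  sc <- field_scaling(stacks)
  beta <- c(0.1, -0.4, -0.2, 0.5, 0.2, -0.3, 0.1)
  t_mid <- stacks$temperature$time[50]
  surf <- predict_gamma_surface(stacks, t_mid, beta, sc)

  grid_track <- tibble::tibble(
    individual_id = "px",
    timestamp = rep(t_mid, nrow(surf)),
    x_km = surf$x, y_km = surf$y)
  ann <- annotate_track(grid_track, stacks) |>
    zero_ndvi_when_snow() |>
    standardize_covariates(scaling = sc)
  Z <- build_design_matrix(ann)
  expect_equal(surf$gamma, linear_predictor(Z, beta, inverse_link = TRUE),
               tolerance = 1e-12)
})
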