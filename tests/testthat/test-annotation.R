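test_that("interpolation identities hold on exact grid points", {
  s <- constant_stack()
  # constant field: any location/time returns the constant
  v <- extract_covariate(s, c(12, 25.5, 30), c(10, 15, 30),
                         rep(s$time[3], 3))
  expect_equal(v, rep(3.5, 3))

  # exact cell center at a slice timestamp returns the stored value
  times <- as.POSIXct("2010-08-15", tz = "UTC") + (0:3) * 3 * 3600
  vals <- array(seq_len(4 * 2 * 2), dim = c(4, 2, 2))
  st <- covariate_stack("v", c(0, 10), c(0, 10), times, vals)
  expect_equal(extract_covariate(st, 10, 0, times[2]),
               vals[2, 1, 2])

  # midpoint of 4 cells valued 1, 2, 3, 4 -> 2.5
  one <- array(0, dim = c(1, 2, 2))
  one[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  st2 <- covariate_stack("v", c(0, 10), c(0, 10), times[1], one)
  expect_equal(extract_covariate(st2, 5, 5, times[1]), 2.5)

  # halfway in time between slices valued 10 and 14 -> 12
  tv <- array(c(10, 14), dim = c(2, 1, 1))
  st3 <- covariate_stack("v", c(0, 1), c(0, 1), times[1:2],
                         array(c(10, 14, 10, 14, 10, 14, 10, 14),
                               dim = c(2, 2, 2)))
  expect_equal(extract_covariate(st3, 0.5, 0.5, times[1] + 1.5 * 3600),
               12)
})

test_that("constant-composite lookup and extent errors behave as specified", {
  s <- constant_stack()
  expect_error(extract_covariate(s, 100, 10, s$time[1]), "extent")
  expect_error(extract_covariate(s, 10, 10, s$time[1] - 86400),
               "time|before")

  # piecewise-constant (composite) time rule: value of containing slice
  times <- as.POSIXct("2010-08-15", tz = "UTC") + c(0, 16, 32) * 86400
  vals <- array(rep(c(1, 2, 3), 4), dim = c(3, 2, 2))
  nd <- covariate_stack("ndvi", c(0, 1), c(0, 1), times, vals,
                        time_rule = "constant")
  expect_equal(extract_covariate(nd, 0.5, 0.5, times[1] + 5 * 86400), 1)
  expect_equal(extract_covariate(nd, 0.5, 0.5, times[2] + 1), 2)
})

test_that("annotation attaches all covariates along a track", {
  stacks <- small_stacks()
  tr <- make_track(n = 8, start = c(200, 200))
  ann <- annotate_track(tr, stacks)
  expect_true(all(c("temperature", "snow", "wind", "ndvi", "pressure")
                  %in% names(ann)))
  expect_true(all(is.finite(as.matrix(
    ann[, c("temperature", "snow", "wind", "ndvi", "pressure")]))))
  # errors name the offending fix
  bad <- make_track(n = 3, start = c(10000, 200))
  expect_error(annotate_track(bad, stacks), "fix 1")
})

test_that("NDVI is zeroed under snow before standardization, idempotently", {
  tbl <- tibble::tibble(ndvi = c(0.42, 0.42, 0.1),
                        snow = c(0.05, 0, 0.3))
  out <- zero_ndvi_when_snow(tbl)
  expect_equal(out$ndvi, c(0, 0.42, 0))
  expect_identical(zero_ndvi_when_snow(out), out)

  all_snow <- tibble::tibble(ndvi = runif(5), snow = rep(0.2, 5))
  expect_true(all(zero_ndvi_when_snow(all_snow)$ndvi == 0))
})

test_that("standardization has unit moments and an exact inverse", {
  tbl <- tibble::tibble(
    individual_id = "a",
    temperature = c(1, 2, 3), snow = c(0, 0.1, 0.3),
    wind = c(2, 4, 9), ndvi = c(0.1, 0.5, 0.9),
    pressure = c(101000, 101300, 101500))
  std <- standardize_covariates(tbl)
  expect_equal(std$temperature_std, c(-1, 0, 1))
  for (v in c("temperature", "snow", "wind", "ndvi", "pressure")) {
    expect_equal(mean(std[[paste0(v, "_std")]]), 0, tolerance = 1e-8)
    expect_equal(sd(std[[paste0(v, "_std")]]), 1, tolerance = 1e-8)
  }
  back <- unstandardize_covariates(std)
  for (v in c("temperature", "snow", "wind", "ndvi", "pressure")) {
    expect_equal(back[[v]], tbl[[v]], tolerance = 1e-10)
  }
  # zero-variance column is a hard error naming the variable
  flat <- dplyr::mutate(tbl, snow = 0)
  expect_error(standardize_covariates(flat), "snow")
})

test_that("design matrix has the canonical 7 columns and interaction", {
  tbl <- tibble::tibble(
    temperature_std = c(0, -2), snow_std = c(0, 1), wind_std = c(0, 0.5),
    ndvi_std = c(0, -1), pressure_std = c(0, 2))
  dm <- build_design_matrix(tbl)
  expect_equal(names(dm), mp_terms())
  expect_equal(ncol(dm), 7)
  expect_equal(unlist(dm[1, ]), setNames(c(1, rep(0, 6)), mp_terms()))
  expect_equal(dm$temperature_snow[2], -2)  # (-2) * 1
  expect_error(build_design_matrix(tbl[, -2]), "snow_std")
})

test_that("correlation screen flags collinear covariates only", {
  set.seed(1)
  n <- 10000
  tbl <- tibble::tibble(
    temperature = rnorm(n), snow = rnorm(n), wind = rnorm(n),
    ndvi = rnorm(n), pressure = rnorm(n))
  cm <- pairwise_correlations(tbl)
  expect_equal(diag(cm), rep(1, 5), ignore_attr = TRUE)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 0.05))

  dup <- dplyr::mutate(tbl, snow = temperature)
  expect_warning(pairwise_correlations(dup), "temperature ~ snow")
})

test_that("design matrix rebuild from metadata is bit-stable", {
  stacks <- small_stacks()
  tr <- make_track(n = 12, start = c(200, 200))
  ann <- annotate_track(tr, stacks) |>
    zero_ndvi_when_snow() |>
    standardize_covariates()
  d1 <- build_design_matrix(ann)
  sc <- attr(ann, "covariate_scaling")
  ann2 <- annotate_track(tr, stacks) |>
    zero_ndvi_when_snow() |>
    standardize_covariates(scaling = sc)
  d2 <- build_design_matrix(ann2)
  expect_identical(as.matrix(d1), as.matrix(d2))
})
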