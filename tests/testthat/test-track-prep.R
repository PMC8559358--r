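write_track_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("parse_tracks reads, sorts and deduplicates Movebank-style CSV", {
  t0 <- as.POSIXct("2010-09-01 00:00:00", tz = "UTC")
  df <- data.frame(
    individual_id = rep(c("a", "b"), each = 10),
    timestamp = format(t0 + c(sample(0:9), 0:9) * 3600 * 8,
                       "%Y-%m-%dT%H:%M:%SZ"),
    x_km = rnorm(20), y_km = rnorm(20)
  )
  out <- parse_tracks(write_track_csv(df))
  expect_equal(nrow(out), 20)
  expect_equal(sort(unique(out$individual_id)), c("a", "b"))
  by_id <- split(out$timestamp, out$individual_id)
  for (ts in by_id) expect_true(all(diff(as.numeric(ts)) > 0))

  # duplicated timestamp collapses to the first row, with a warning
  df2 <- df[c(1, 1, 2:10), ]
  expect_warning(out2 <- parse_tracks(write_track_csv(df2)), "duplicated")
  expect_equal(sum(out2$individual_id == "a"), 10)

  # missing columns fail loudly
  expect_error(parse_tracks(write_track_csv(df[, -1])), "individual_id")
  expect_error(parse_tracks(write_track_csv(df[, 1:2])), "x_km")

  # more than 1% unparseable timestamps aborts
  df3 <- df
  df3$timestamp[1:5] <- "not-a-time"
  expect_error(suppressWarnings(parse_tracks(write_track_csv(df3))),
               "unparseable")
})

test_that("projection is invertible and metrically faithful near 67N", {
  skip_if_not_installed("geosphere")
  d <- tibble::tibble(
    individual_id = "a",
    lon = c(-160, -159.5, -160, -158),
    lat = c(66.5, 67, 67.5, 68)
  )
  p <- project_coordinates(d)
  expect_true(all(c("x_km", "y_km") %in% names(p)))

  # round trip within 1 m
  back <- unproject_coordinates(p)
  expect_lt(max(abs(back$lon - d$lon)), 1e-5)
  expect_lt(max(abs(back$lat - d$lat)), 1e-5)

  # 1 degree of latitude near 67 N spans ~111 km (geodesic oracle)
  two <- project_coordinates(
    tibble::tibble(lon = c(-160, -160), lat = c(66.5, 67.5)))
  planar <- sqrt(diff(two$x_km)^2 + diff(two$y_km)^2)
  geo <- geosphere::distGeo(c(-160, 66.5), c(-160, 67.5)) / 1000
  expect_lt(abs(planar - geo) / geo, 0.01)

  # planar input passes through unchanged
  pl <- tibble::tibble(individual_id = "a", x_km = 1:3, y_km = 4:6)
  expect_identical(project_coordinates(pl), pl)

  # out-of-range coordinates rejected
  expect_error(project_coordinates(
    tibble::tibble(lon = c(-200, 0), lat = c(0, 0))), "range")
})

test_that("subsampling to 8 h keeps the nearest fix per grid slot", {
  t0 <- as.POSIXct("2010-09-01 00:00:00", tz = "UTC")

  # 2-h data over 46 h -> slots at 0, 8, ..., 40 h
  tr <- tibble::tibble(individual_id = "a",
                       timestamp = t0 + seq(0, 46, by = 2) * 3600,
                       x_km = 0, y_km = 0)
  out <- subsample_to_interval(tr, 8, 1)
  expect_equal(as.numeric(out$timestamp - t0, units = "hours"),
               c(0, 8, 16, 24, 32, 40))

  # already regular: identity
  reg <- make_track(n = 6)
  expect_equal(subsample_to_interval(reg)$timestamp, reg$timestamp)

  # a fix 1 h off-grid is matched to its slot and retained
  tr2 <- tibble::tibble(individual_id = "a",
                        timestamp = t0 + c(0, 8, 17, 24) * 3600,
                        x_km = 0, y_km = 0)
  out2 <- subsample_to_interval(tr2, 8, 1)
  expect_equal(as.numeric(out2$timestamp - t0, units = "hours"),
               c(0, 8, 17, 24))

  # idempotence
  once <- subsample_to_interval(tr2, 8, 1)
  expect_equal(subsample_to_interval(once, 8, 1)$timestamp,
               once$timestamp)

  expect_error(subsample_to_interval(reg, 8, 5), "tol")
})

test_that("season clipping is inclusive and supports the truncated window", {
  mk <- function(dates) tibble::tibble(
    individual_id = "a", season_year = 2010L,
    timestamp = as.POSIXct(dates, tz = "UTC"), x_km = 0, y_km = 0)

  tr <- mk(c("2010-08-01 12:00:00", "2010-09-01 12:00:00",
             "2011-01-05 12:00:00"))
  expect_equal(format(clip_to_season(tr)$timestamp, "%Y-%m-%d"),
               "2010-09-01")

  # boundary fix retained (inclusive)
  edge <- mk("2010-08-15 00:00:00")
  expect_equal(nrow(clip_to_season(edge)), 1)

  # truncated variant drops December
  dec <- mk(c("2010-10-01 00:00:00", "2010-12-10 00:00:00"))
  expect_equal(nrow(clip_to_season(dec, truncated = TRUE)), 1)
  expect_equal(nrow(clip_to_season(dec)), 2)
})

test_that("expected fix counts follow calendar arithmetic", {
  # Aug 15 00:00 -> Dec 31 23:59 at 8 h: 138 full days plus 23:59,
  # i.e. floor(3335.98 / 8) + 1 = 417 (independent calendar oracle)
  expect_equal(expected_fix_count("2010-08-15 00:00:00",
                                  "2010-12-31 23:59:00", 8), 417L)
  expect_equal(expected_fix_count("2010-09-01 00:00:00",
                                  "2010-09-02 00:00:00", 8), 4L)
  expect_equal(expected_fix_count("2010-09-01 00:00:00",
                                  "2010-09-01 05:00:00", 8), 1L)
  expect_error(expected_fix_count("2010-09-02", "2010-09-01"), "precede")
})

test_that("inclusion rules exclude deaths, late deployments and sparse data", {
  t0 <- as.POSIXct("2010-08-15 00:00:00", tz = "UTC")
  full <- tibble::tibble(
    individual_id = "complete", season_year = 2010L,
    timestamp = t0 + (0:416) * 8 * 3600, x_km = 0, y_km = 0,
    died_in_season = FALSE, deployed_mid_season = FALSE)
  sparse <- dplyr::mutate(full[1:200, ], individual_id = "sparse")
  died <- dplyr::mutate(full, individual_id = "died",
                        died_in_season = TRUE)
  late <- dplyr::mutate(full, individual_id = "late",
                        deployed_mid_season = TRUE)

  res <- apply_inclusion_rules(dplyr::bind_rows(full, sparse, died, late))
  expect_setequal(unique(res$retained$individual_id), "complete")
  ex <- res$exclusions
  expect_equal(ex$reason[ex$individual_id == "sparse"],
               "insufficient_fixes")
  expect_equal(ex$reason[ex$individual_id == "died"], "died_in_season")
  expect_equal(ex$reason[ex$individual_id == "late"],
               "deployed_mid_season")
  # 200 < 0.5 * 417 = 208.5 -> excluded; exactly one reason each
  expect_equal(ex$expected[ex$individual_id == "sparse"], 417)
  expect_equal(nrow(ex), 3)
})
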