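#' Read Movebank-style relocation data
#'
#' Parses a CSV of GPS fixes into a tidy track table. Required columns:
#' `individual_id`, `timestamp` (ISO-8601, UTC), and either planar
#' `x_km`/`y_km` or geographic `location-long`/`location-lat` (also
#' accepted as `location.long`/`location_long` variants). Optional logical
#' flag columns `died_in_season` and `deployed_mid_season` are carried
#' through. Rows are sorted by time within individual; duplicate
#' timestamps keep the first occurrence (with a warning); rows with
#' unparseable timestamps are dropped with a warning unless they exceed
#' 1\% of the file, in which case parsing fails.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per fix and a `season_year` column
#'   (calendar year of the fix).
#' @export
parse_tracks <- function(path) {
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE))
  names(df) <- gsub("[.]", "-", names(df))
  names(df)[names(df) == "location-long"] <- "lon"
  names(df)[names(df) == "location-lat"] <- "lat"
  names(df)[names(df) == "location_long"] <- "lon"
  names(df)[names(df) == "location_lat"] <- "lat"
  required <- c("individual_id", "timestamp")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  if (!all(c("x_km", "y_km") %in% names(df)) &&
      !all(c("lon", "lat") %in% names(df))) {
    stop("need either x_km/y_km or location-long/location-lat columns")
  }

  raw_ts <- as.character(df$timestamp)
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw_ts[todo], fmt, tz = "UTC"))
  }
  bad <- is.na(ts) & !is.na(df$timestamp)
  if (any(bad)) {
    if (mean(bad) > 0.01) {
      stop(sprintf("%d of %d rows (%.1f%%) have unparseable timestamps",
                   sum(bad), nrow(df), 100 * mean(bad)))
    }
    warning(sprintf("dropped %d rows with unparseable timestamps (rows %s)",
                    sum(bad),
                    paste(head(which(bad), 5), collapse = ", ")))
  }
  df$timestamp <- ts
  df <- df[!is.na(ts), ]

  for (flag in c("died_in_season", "deployed_mid_season")) {
    if (!flag %in% names(df)) df[[flag]] <- FALSE
    df[[flag]] <- as.logical(df[[flag]])
    df[[flag]][is.na(df[[flag]])] <- FALSE
  }

  df <- dplyr::arrange(df, .data$individual_id, .data$timestamp)
  dup <- duplicated(df[c("individual_id", "timestamp")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated timestamps to first fix",
                    sum(dup)))
    df <- df[!dup, ]
  }
  df$season_year <- as.integer(format(df$timestamp, "%Y"))
  tibble::as_tibble(df)
}

# spherical Albers equal-area conic (authalic radius); params chosen from
# the data extent by the 1/6 rule when not supplied
albers_params <- function(lon, lat) {
  rlat <- range(lat)
  list(R = 6371.0072,
       lat1 = rlat[1] + diff(rlat) / 6,
       lat2 = rlat[2] - diff(rlat) / 6,
       lon0 = mean(range(lon)), lat0 = mean(rlat))
}

albers_forward <- function(lon, lat, p) {
  d <- pi / 180
  n <- (sin(p$lat1 * d) + sin(p$lat2 * d)) / 2
  if (abs(n) < 1e-9) stop("degenerate standard parallels")
  C <- cos(p$lat1 * d)^2 + 2 * n * sin(p$lat1 * d)
  rho <- p$R / n * sqrt(pmax(C - 2 * n * sin(lat * d), 0))
  rho0 <- p$R / n * sqrt(max(C - 2 * n * sin(p$lat0 * d), 0))
  th <- n * (lon - p$lon0) * d
  list(x = rho * sin(th), y = rho0 - rho * cos(th))
}

albers_inverse <- function(x, y, p) {
  d <- pi / 180
  n <- (sin(p$lat1 * d) + sin(p$lat2 * d)) / 2
  C <- cos(p$lat1 * d)^2 + 2 * n * sin(p$lat1 * d)
  rho0 <- p$R / n * sqrt(max(C - 2 * n * sin(p$lat0 * d), 0))
  rho <- sqrt(x^2 + (rho0 - y)^2)
  th <- atan2(x, rho0 - y)
  lat <- asin((C - (rho * n / p$R)^2) / (2 * n)) / d
  lon <- p$lon0 + th / (n * d)
  list(lon = lon, lat = lat)
}

#' Project geographic coordinates to planar km
#'
#' Adds `x_km`/`y_km` columns using a spherical Albers equal-area conic
#' projection centered on the data (standard parallels by the 1/6 rule).
#' Input that already carries `x_km`/`y_km` is returned unchanged. The
#' projection parameters are attached as attribute `"projection"` so the
#' transform is invertible (see [unproject_coordinates()]).
#'
#' @param data A tibble with `lon`/`lat` columns in decimal degrees
#'   (longitude in \[-180, 180\], latitude in \[-90, 90\]).
#' @param params Optional projection parameter list (from a previous
#'   call's attribute) to reuse a fixed projection.
#' @return The tibble with `x_km`, `y_km` columns added.
#' @export
project_coordinates <- function(data, params = NULL) {
  if (all(c("x_km", "y_km") %in% names(data))) return(data)
  if (!all(c("lon", "lat") %in% names(data))) {
    stop("need lon/lat columns to project")
  }
  if (any(data$lon < -180 | data$lon > 180, na.rm = TRUE) ||
      any(data$lat < -90 | data$lat > 90, na.rm = TRUE)) {
    stop("lon/lat out of range")
  }
  if (is.null(params)) params <- albers_params(data$lon, data$lat)
  xy <- albers_forward(data$lon, data$lat, params)
  data$x_km <- xy$x
  data$y_km <- xy$y
  attr(data, "projection") <- params
  data
}

#' Invert the planar projection back to lon/lat
#'
#' @param data A tibble with `x_km`/`y_km` and a `"projection"` attribute
#'   (or explicit `params`).
#' @param params Projection parameter list.
#' @return The tibble with `lon`/`lat` columns set.
#' @export
unproject_coordinates <- function(data, params = attr(data, "projection")) {
  if (is.null(params)) stop("no projection parameters available")
  ll <- albers_inverse(data$x_km, data$y_km, params)
  data$lon <- ll$lon
  data$lat <- ll$lat
  data
}

#' Subsample a track to a regular fix interval
#'
#' For consistency across collars programmed at different duty cycles,
#' fixes are thinned to a target interval (default 8 h). The grid is
#' anchored at each individual-season's first fix; for every grid time
#' the nearest fix within `tol_h` is retained and all others dropped.
#' The operation is idempotent.
#'
#' @param track Tibble of fixes (may contain several individuals; the
#'   rule is applied per `individual_id` x `season_year` group).
#' @param target_h Target interval in hours.
#' @param tol_h Matching tolerance in hours; must be < `target_h / 2`.
#' @return The subsampled tibble.
#' @export
subsample_to_interval <- function(track, target_h = 8, tol_h = 1) {
  stopifnot(target_h > 0, tol_h < target_h / 2)
  one <- function(d, ...) {
    d <- dplyr::arrange(d, .data$timestamp)
    t0 <- as.numeric(d$timestamp[1])
    rel <- (as.numeric(d$timestamp) - t0) / 3600
    slot <- round(rel / target_h)
    off <- abs(rel - slot * target_h)
    d$.slot <- slot
    d$.off <- off
    d <- d[d$.off <= tol_h + 1e-9, ]
    d <- dplyr::slice_min(dplyr::group_by(d, .data$.slot), .data$.off,
                          n = 1, with_ties = FALSE)
    d <- dplyr::ungroup(d)
    d <- dplyr::arrange(d, .data$timestamp)
    d$.slot <- NULL
    d$.off <- NULL
    if (nrow(d) == 0) stop("subsampling produced an empty track")
    d
  }
  grp <- intersect(c("individual_id", "season_year"), names(track))
  if (length(grp)) {
    track |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::group_modify(one) |>
      dplyr::ungroup()
  } else {
    one(track)
  }
}

# season window for a given year; truncated variant ends Nov 15
season_window <- function(year, truncated = FALSE) {
  list(
    start = as_utc(sprintf("%d-08-15 00:00:00", year)),
    end = as_utc(sprintf(if (truncated) "%d-11-15 23:59:59"
                         else "%d-12-31 23:59:59", year))
  )
}

#' Clip fixes to the autumn season window
#'
#' Retains fixes within the analysis window, boundaries inclusive. The
#' default window is August 15 through December 31 of each track's
#' `season_year`; the truncated sensitivity variant ends November 15.
#'
#' @param track Tibble of fixes.
#' @param start,end Optional explicit window bounds (`POSIXct` or
#'   parseable strings); when omitted, the per-season default applies.
#' @param truncated Use the November-15 end date.
#' @return The clipped tibble (possibly empty).
#' @export
clip_to_season <- function(track, start = NULL, end = NULL,
                           truncated = FALSE) {
  if (!is.null(start) && !is.null(end)) {
    start <- as_utc(start); end <- as_utc(end)
    if (start >= end) stop("start must precede end")
    return(dplyr::filter(track, .data$timestamp >= start,
                         .data$timestamp <= end))
  }
  yr <- if ("season_year" %in% names(track)) track$season_year
        else as.integer(format(track$timestamp, "%Y"))
  win <- lapply(yr, season_window, truncated = truncated)
  keep <- mapply(function(t, w) t >= w$start && t <= w$end,
                 track$timestamp, win)
  track[keep, , drop = FALSE]
}

#' Expected number of fixes in a window
#'
#' Number of regular interval grid points that fit in `[start, end]`,
#' counting the one at `start`: the denominator of the "less than half of
#' the expected locations" inclusion rule.
#'
#' @param start,end Window bounds (`POSIXct` or parseable strings).
#' @param interval_h Fix interval in hours.
#' @return Integer count.
#' @export
expected_fix_count <- function(start, end, interval_h = 8) {
  start <- as_utc(start); end <- as_utc(end)
  if (start >= end) stop("start must precede end")
  hours <- as.numeric(difftime(end, start, units = "hours"))
  as.integer(floor(hours / interval_h + 1e-9)) + 1L
}

#' Apply individual-season inclusion rules
#'
#' An individual-season is excluded when the individual died during the
#' season, was collared mid-season, or retained fewer than half of the
#' expected fixes for the analysis window. Each exclusion carries exactly
#' one primary reason (mortality takes precedence over mid-season
#' deployment, which takes precedence over missing data).
#'
#' @param tracks Tibble of fixes with `individual_id`, `season_year` and
#'   flag columns (`died_in_season`, `deployed_mid_season`; absent flags
#'   are treated as `FALSE`).
#' @param interval_h Fix interval used for the expected count.
#' @param truncated Use the truncated (Nov 15) window for the expected
#'   count.
#' @return A list with `retained` (tibble of fixes) and `exclusions`
#'   (tibble: `individual_id`, `season_year`, `reason`, `n_fixes`,
#'   `expected`).
#' @export
apply_inclusion_rules <- function(tracks, interval_h = 8,
                                  truncated = FALSE) {
  for (flag in c("died_in_season", "deployed_mid_season")) {
    if (!flag %in% names(tracks)) tracks[[flag]] <- FALSE
  }
  if (!"season_year" %in% names(tracks)) {
    tracks$season_year <- as.integer(format(tracks$timestamp, "%Y"))
  }
  summary <- tracks |>
    dplyr::group_by(.data$individual_id, .data$season_year) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      died = any(.data$died_in_season),
      mid = any(.data$deployed_mid_season),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      expected = {
        w <- season_window(.data$season_year, truncated)
        expected_fix_count(w$start, w$end, interval_h)
      },
      reason = dplyr::case_when(
        died ~ "died_in_season",
        mid ~ "deployed_mid_season",
        n_fixes < 0.5 * expected ~ "insufficient_fixes",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::ungroup()

  exclusions <- summary |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("individual_id", "season_year", "reason", "n_fixes",
                  "expected")
  retained <- dplyr::anti_join(
    tracks, exclusions, by = c("individual_id", "season_year"))
  list(retained = tibble::as_tibble(retained), exclusions = exclusions)
}
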