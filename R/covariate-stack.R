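#' Gridded covariate stack
#'
#' A lightweight container for one environmental variable on a regular
#' planar grid with a time axis: `values[t, iy, ix]` holds the field at
#' `time[t]`, `y[iy]`, `x[ix]`. Weather variables (temperature, snow, wind,
#' pressure) carry a 3-h time axis interpolated linearly in time; NDVI
#' carries 16-day composite start times and is looked up as the value of
#' the containing composite.
#'
#' @param variable Variable name (e.g. `"temperature"`).
#' @param x,y Numeric vectors of strictly increasing cell-center
#'   coordinates in km.
#' @param time `POSIXct` vector of strictly increasing timestamps (UTC).
#' @param values Numeric array with dim `c(length(time), length(y),
#'   length(x))`; no missing values allowed inside the declared extent.
#' @param units Unit string recorded as metadata.
#' @param time_rule `"linear"` for linear interpolation between bracketing
#'   slices, `"constant"` for piecewise-constant lookup of the containing
#'   composite (NDVI).
#'
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(variable, x, y, time, values, units = "",
                            time_rule = c("linear", "constant")) {
  time_rule <- match.arg(time_rule)
  time <- as_utc(time)
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2, length(y) >= 2)
  if (any(diff(x) <= 0) || any(diff(y) <= 0)) {
    stop("grid coordinates must be strictly increasing")
  }
  if (length(time) < 1 || any(diff(as.numeric(time)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (!identical(dim(values), c(length(time), length(y), length(x)))) {
    stop("values must have dim (time, y, x) = (",
         length(time), ", ", length(y), ", ", length(x), ")")
  }
  if (anyNA(values)) stop("covariate values contain NA inside the extent")
  structure(
    list(variable = variable, x = x, y = y, time = time,
         values = values, units = units, time_rule = time_rule),
    class = "covariate_stack"
  )
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf(
    "<covariate_stack> %s [%s]: %d x %d grid, %d time slices (%s)\n",
    x$variable, x$units, length(x$x), length(x$y), length(x$time),
    x$time_rule))
  invisible(x)
}

# fractional index of v in strictly increasing centers; error if outside
grid_fraction <- function(v, centers, what, context) {
  if (any(v < centers[1] - 1e-9) || any(v > centers[length(centers)] + 1e-9)) {
    bad <- which(v < centers[1] - 1e-9 | v > centers[length(centers)] + 1e-9)[1]
    stop(sprintf("%s outside %s extent (value %.3f, extent [%.3f, %.3f])",
                 context[bad], what, v[bad], centers[1],
                 centers[length(centers)]))
  }
  idx <- findInterval(v, centers, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(centers) - 1L)
  frac <- (v - centers[idx]) / (centers[idx + 1L] - centers[idx])
  list(i = idx, f = pmin(pmax(frac, 0), 1))
}

#' Extract covariate values at points in space and time
#'
#' Bilinear interpolation over the four surrounding cell centers, combined
#' with linear interpolation in time between bracketing slices (or the
#' containing composite's value when the stack's `time_rule` is
#' `"constant"`).
#'
#' @param stack A [covariate_stack()].
#' @param x,y Planar coordinates (km) of the query points.
#' @param time `POSIXct` query timestamps.
#' @param context Optional character labels used in error messages (e.g.
#'   `"fix 12"`).
#' @return Numeric vector of interpolated values.
#' @export
extract_covariate <- function(stack, x, y, time, context = NULL) {
  stopifnot(inherits(stack, "covariate_stack"))
  n <- length(x)
  time <- as_utc(time)
  if (length(y) != n || length(time) != n) {
    stop("x, y and time must have equal length")
  }
  if (is.null(context)) context <- paste0("point ", seq_len(n))
  context <- paste0(context, " [", stack$variable, "]")

  gx <- grid_fraction(x, stack$x, "x", context)
  gy <- grid_fraction(y, stack$y, "y", context)

  tnum <- as.numeric(time)
  snum <- as.numeric(stack$time)
  if (stack$time_rule == "constant") {
    # value of the containing composite; last composite extends to the
    # stack's declared end (a query before the first slice is an error)
    if (any(tnum < snum[1] - 1e-6)) {
      bad <- which(tnum < snum[1] - 1e-6)[1]
      stop(sprintf("%s is before the first time slice", context[bad]))
    }
    ti <- findInterval(tnum, snum)
    wt <- rep(0, n)
    ti2 <- ti
  } else {
    if (any(tnum < snum[1] - 1e-6) || any(tnum > snum[length(snum)] + 1e-6)) {
      bad <- which(tnum < snum[1] - 1e-6 | tnum > snum[length(snum)] + 1e-6)[1]
      stop(sprintf("%s outside the stack's time range", context[bad]))
    }
    if (length(snum) == 1L) {
      ti <- rep(1L, n); ti2 <- ti; wt <- rep(0, n)
    } else {
      ti <- findInterval(tnum, snum, rightmost.closed = TRUE)
      ti <- pmin(pmax(ti, 1L), length(snum) - 1L)
      ti2 <- ti + 1L
      wt <- (tnum - snum[ti]) / (snum[ti2] - snum[ti])
      wt <- pmin(pmax(wt, 0), 1)
    }
  }

  bilin_at <- function(tidx) {
    v00 <- stack$values[cbind(tidx, gy$i,      gx$i)]
    v01 <- stack$values[cbind(tidx, gy$i,      gx$i + 1L)]
    v10 <- stack$values[cbind(tidx, gy$i + 1L, gx$i)]
    v11 <- stack$values[cbind(tidx, gy$i + 1L, gx$i + 1L)]
    (1 - gy$f) * ((1 - gx$f) * v00 + gx$f * v01) +
      gy$f * ((1 - gx$f) * v10 + gx$f * v11)
  }
  (1 - wt) * bilin_at(ti) + wt * bilin_at(ti2)
}

#' Serialize covariate stacks to a long-format data frame
#'
#' @param stacks Named list of [covariate_stack()] objects.
#' @return A tibble with columns `variable, time, y, x, value, units,
#'   time_rule`, suitable for CSV round-tripping via
#'   [stacks_from_long()].
#' @export
stacks_to_long <- function(stacks) {
  purrr::map_dfr(stacks, function(s) {
    grid <- expand.grid(x = s$x, y = s$y, time = s$time,
                        KEEP.OUT.ATTRS = FALSE)
    # values indexed [time, y, x]; expand.grid varies x fastest
    v <- aperm(s$values, c(3, 2, 1))
    tibble::tibble(
      variable = s$variable,
      time = as_utc(grid$time),
      y = grid$y, x = grid$x,
      value = as.vector(v),
      units = s$units, time_rule = s$time_rule
    )
  })
}

#' Rebuild covariate stacks from long format
#'
#' Inverse of [stacks_to_long()].
#'
#' @param df Data frame as produced by [stacks_to_long()].
#' @return Named list of [covariate_stack()] objects.
#' @export
stacks_from_long <- function(df) {
  split(df, df$variable) |>
    purrr::map(function(d) {
      x <- sort(unique(d$x)); y <- sort(unique(d$y))
      time <- sort(unique(as_utc(d$time)))
      d <- d[order(as.numeric(as_utc(d$time)), d$y, d$x), ]
      v <- array(d$value, dim = c(length(x), length(y), length(time)))
      covariate_stack(d$variable[1], x, y, time,
                      aperm(v, c(3, 2, 1)),
                      units = d$units[1], time_rule = d$time_rule[1])
    })
}
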