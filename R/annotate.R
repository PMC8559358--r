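#' Annotate fixes with environmental covariates
#'
#' Attaches the raw value of each covariate stack to every fix by
#' bilinear interpolation over the four surrounding cell centers and
#' linear interpolation in time between bracketing slices; NDVI uses the
#' value of the containing 16-day composite.
#'
#' @param track Tibble of fixes with `x_km`, `y_km`, `timestamp`.
#' @param stacks Named list of [covariate_stack()]s (needs all of
#'   `temperature`, `snow`, `wind`, `ndvi`, `pressure`).
#' @return The tibble with one raw column added per covariate.
#' @export
annotate_track <- function(track, stacks) {
  missing <- setdiff(mp_variables(), names(stacks))
  if (length(missing)) {
    stop("missing covariate stacks: ", paste(missing, collapse = ", "))
  }
  ctx <- sprintf("fix %d (%s)", seq_len(nrow(track)),
                 format(track$timestamp, "%Y-%m-%d %H:%M"))
  for (v in mp_variables()) {
    track[[v]] <- extract_covariate(stacks[[v]], track$x_km, track$y_km,
                                    track$timestamp, context = ctx)
  }
  track
}

#' Zero NDVI under snow
#'
#' Sets the raw NDVI value to 0 wherever snow depth is positive, before
#' standardization: in Arctic autumns snow cover, not senescence alone,
#' drives much of the seasonal NDVI signal, so a snow-covered pixel's
#' greenness is treated as absent. Idempotent.
#'
#' @param table Tibble with `ndvi` and `snow` columns.
#' @return The tibble with `ndvi` zeroed where `snow > 0`.
#' @export
zero_ndvi_when_snow <- function(table) {
  stopifnot(all(c("ndvi", "snow") %in% names(table)))
  dplyr::mutate(table, ndvi = ifelse(.data$snow > 0, 0, .data$ndvi))
}

#' Standardize covariates to mean zero, unit variance
#'
#' Adds `*_std` columns for the five raw covariates. Moments are pooled
#' over the supplied scope: `"pooled"` (default; all rows, making
#' individual coefficients commensurable within a year) or
#' `"individual"` (per `individual_id`). Alternatively a fixed `scaling`
#' table can be supplied (e.g. [field_scaling()] of the generating
#' stacks) to share one reference between simulation and fitting. The
#' scaling used is attached as attribute `"covariate_scaling"` for
#' back-transformation.
#'
#' @param table Annotated tibble (raw covariate columns present).
#' @param scope `"pooled"` or `"individual"`.
#' @param scaling Optional fixed tibble (`variable`, `mean`, `sd`).
#' @return The tibble with standardized columns and scaling attribute.
#' @export
standardize_covariates <- function(table, scope = c("pooled", "individual"),
                                   scaling = NULL) {
  scope <- match.arg(scope)
  vars <- mp_variables()
  stopifnot(all(vars %in% names(table)))
  if (is.null(scaling)) {
    if (scope == "individual") {
      out <- table |>
        dplyr::group_by(.data$individual_id) |>
        dplyr::group_modify(~ standardize_covariates(.x, "pooled")) |>
        dplyr::ungroup()
      return(out)
    }
    scaling <- purrr::map_dfr(vars, function(v) {
      m <- mean(table[[v]]); s <- stats::sd(table[[v]])
      if (!is.finite(s) || s == 0) {
        stop(sprintf("covariate '%s' has zero variance; cannot standardize",
                     v))
      }
      tibble::tibble(variable = v, mean = m, sd = s)
    })
  }
  for (v in vars) {
    row <- scaling[scaling$variable == v, ]
    if (nrow(row) != 1) stop("scaling table lacks variable ", v)
    table[[paste0(v, "_std")]] <- (table[[v]] - row$mean) / row$sd
  }
  attr(table, "covariate_scaling") <- scaling
  table
}

#' Back-transform standardized covariates
#'
#' @param table Tibble with `*_std` columns and a `"covariate_scaling"`
#'   attribute (or explicit `scaling`).
#' @param scaling Tibble (`variable`, `mean`, `sd`).
#' @return The tibble with raw columns recomputed from the standardized
#'   ones.
#' @export
unstandardize_covariates <- function(table,
                                     scaling = attr(table,
                                                    "covariate_scaling")) {
  if (is.null(scaling)) stop("no covariate scaling available")
  for (v in mp_variables()) {
    row <- scaling[scaling$variable == v, ]
    table[[v]] <- table[[paste0(v, "_std")]] * row$sd + row$mean
  }
  table
}

#' Build the 7-column persistence design matrix
#'
#' Assembles `Z = (1, temp, snow, temp x snow, wind, ndvi, pressure)`
#' from standardized columns; the interaction is the elementwise product
#' of the two standardized main effects.
#'
#' @param table Tibble with `*_std` columns (see
#'   [standardize_covariates()]).
#' @return A tibble of 7 design columns named as [mp_terms()], carrying
#'   the `"covariate_scaling"` attribute through.
#' @export
build_design_matrix <- function(table) {
  std <- paste0(mp_variables(), "_std")
  missing <- setdiff(std, names(table))
  if (length(missing)) {
    stop("missing standardized columns: ", paste(missing, collapse = ", "))
  }
  out <- tibble::tibble(
    intercept = rep(1, nrow(table)),
    temperature = table$temperature_std,
    snow = table$snow_std,
    temperature_snow = table$temperature_std * table$snow_std,
    wind = table$wind_std,
    ndvi = table$ndvi_std,
    pressure = table$pressure_std
  )
  attr(out, "covariate_scaling") <- attr(table, "covariate_scaling")
  out
}

#' Pairwise correlations among raw covariates
#'
#' Pearson correlations among the five raw main-effect covariates; the
#' conventional collinearity screen warns (without aborting) when any
#' absolute off-diagonal correlation reaches 0.7.
#'
#' @param table Annotated tibble (>= 3 rows).
#' @param threshold Warning threshold on `|r|`.
#' @return The 5x5 correlation matrix (invisibly warns on high values).
#' @export
pairwise_correlations <- function(table, threshold = 0.7) {
  vars <- mp_variables()
  stopifnot(all(vars %in% names(table)), nrow(table) >= 3)
  cm <- stats::cor(as.matrix(table[vars]))
  hi <- which(abs(cm) >= threshold & upper.tri(cm), arr.ind = TRUE)
  if (nrow(hi)) {
    msgs <- apply(hi, 1, function(ij) {
      sprintf("%s ~ %s (r = %.2f)", vars[ij[1]], vars[ij[2]],
              cm[ij[1], ij[2]])
    })
    warning("high covariate correlations: ", paste(msgs, collapse = "; "))
  }
  cm
}
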