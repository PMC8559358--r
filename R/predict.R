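#' Predict the persistence surface over a landscape
#'
#' For every grid cell at one time, standardizes the raw covariate
#' fields with the stored training means/sds, applies the
#' NDVI-under-snow zeroing, forms the 7-term design vector and returns
#' `gamma_hat = plogis(Z' beta_p)` -- the landscape map of expected
#' migratory movement.
#'
#' @param stacks Named list of [covariate_stack()]s covering the grid.
#' @param time Timestamp at which to evaluate the fields.
#' @param beta_p Length-7 posterior-mean coefficient vector, or a
#'   draws x 7 matrix (then `realizations` per-draw surfaces are
#'   returned in long format).
#' @param scaling Standardization table (`variable`, `mean`, `sd`) from
#'   the fit.
#' @param ndvi_zeroing Apply the NDVI-under-snow rule (kept consistent
#'   with training).
#' @param realizations Number of per-draw surfaces when `beta_p` is a
#'   matrix (0 = posterior-mean surface only).
#' @return A tibble with `x`, `y`, `gamma` (`draw = 0` for the mean
#'   surface, 1..`realizations` for posterior realizations).
#' @export
predict_gamma_surface <- function(stacks, time, beta_p, scaling,
                                  ndvi_zeroing = TRUE, realizations = 0) {
  time <- as_utc(time)
  grid <- expand.grid(x = stacks$temperature$x, y = stacks$temperature$y,
                      KEEP.OUT.ATTRS = FALSE)
  raw <- purrr::map(stacks[mp_variables()], extract_covariate,
                    x = grid$x, y = grid$y,
                    time = rep(time, nrow(grid)))
  if (ndvi_zeroing) raw$ndvi[raw$snow > 0] <- 0
  std <- purrr::imap(raw, function(v, nm) {
    row <- scaling[scaling$variable == nm, ]
    if (nrow(row) != 1) stop("scaling table lacks variable ", nm)
    (v - row$mean) / row$sd
  })
  Z <- cbind(1, std$temperature, std$snow,
             std$temperature * std$snow, std$wind, std$ndvi,
             std$pressure)
  colnames(Z) <- mp_terms()

  if (is.matrix(beta_p)) {
    bmean <- colMeans(beta_p)
    out <- tibble::tibble(x = grid$x, y = grid$y, draw = 0L,
                          gamma = inv_logit(drop(Z %*% bmean)))
    if (realizations > 0) {
      idx <- round(seq(1, nrow(beta_p), length.out = realizations))
      extra <- purrr::map_dfr(seq_along(idx), function(r) {
        tibble::tibble(x = grid$x, y = grid$y, draw = r,
                       gamma = inv_logit(drop(Z %*% beta_p[idx[r], ])))
      })
      out <- dplyr::bind_rows(out, extra)
    }
    out
  } else {
    if (length(beta_p) != 7) stop("beta_p must have 7 elements")
    tibble::tibble(x = grid$x, y = grid$y, draw = 0L,
                   gamma = inv_logit(drop(Z %*% beta_p)))
  }
}

#' Temperature-response curves at fixed snow depths
#'
#' The predicted persistence as a function of temperature at chosen snow
#' depths (defaults: no snow = 0 cm, average snow = 11 cm, deep
#' snow = 46 cm), with the remaining covariates held at their training
#' means (standardized 0). One curve per posterior draw
#' (`gamma^(l) = plogis(Z' beta_p^(l))`) plus the posterior-mean curve
#' (`draw = 0`).
#'
#' @param beta_p Draws x 7 matrix of population-level coefficients (a
#'   length-7 vector yields the mean curve only).
#' @param scaling Standardization table; snow mean/sd are used to
#'   standardize the cm levels (snow stored in meters), temperature
#'   mean/sd to standardize the temperature grid (degC).
#' @param temp_c Temperature grid in degC.
#' @param snow_cm Snow-depth levels in cm.
#' @param max_draws Cap on the number of per-draw curves returned.
#' @return A tibble `snow_cm`, `temp_c`, `draw` (0 = mean), `gamma`.
#' @export
temperature_response_curves <- function(beta_p, scaling,
                                        temp_c = seq(-35, 20, by = 0.5),
                                        snow_cm = c(0, 11, 46),
                                        max_draws = 200) {
  srow <- scaling[scaling$variable == "snow", ]
  trow <- scaling[scaling$variable == "temperature", ]
  if (nrow(srow) != 1 || nrow(trow) != 1) {
    stop("scaling table must contain snow and temperature rows")
  }
  if (srow$sd <= 0) stop("snow sd is zero; cannot standardize levels")
  if (!is.matrix(beta_p)) beta_p <- matrix(beta_p, nrow = 1)
  if (ncol(beta_p) != 7) stop("beta_p must have 7 columns")

  t_std <- (temp_c - trow$mean) / trow$sd
  grid <- purrr::map_dfr(snow_cm, function(s) {
    s_std <- (s / 100 - srow$mean) / srow$sd
    tibble::tibble(snow_cm = s, temp_c = temp_c, t_std = t_std,
                   s_std = s_std)
  })
  Z <- cbind(1, grid$t_std, grid$s_std, grid$t_std * grid$s_std, 0, 0, 0)

  bmean <- colMeans(beta_p)
  out <- tibble::tibble(snow_cm = grid$snow_cm, temp_c = grid$temp_c,
                        draw = 0L, gamma = inv_logit(drop(Z %*% bmean)))
  if (nrow(beta_p) > 1) {
    idx <- if (nrow(beta_p) > max_draws) {
      round(seq(1, nrow(beta_p), length.out = max_draws))
    } else {
      seq_len(nrow(beta_p))
    }
    per_draw <- purrr::map_dfr(seq_along(idx), function(r) {
      tibble::tibble(snow_cm = grid$snow_cm, temp_c = grid$temp_c,
                     draw = r,
                     gamma = inv_logit(drop(Z %*% beta_p[idx[r], ])))
    })
    out <- dplyr::bind_rows(out, per_draw)
  }
  out
}

#' Snow depth at which the temperature effect inverts
#'
#' With the interaction present, the marginal temperature slope on the
#' logit scale is `beta_1 + beta_3 * snow_std`; it changes sign at
#' `snow_std = -beta_1 / beta_3`, i.e. at depth
#' `snow_mean + snow_sd * (-beta_1 / beta_3)`. Below that depth colder
#' temperatures increase persistence; above it the relationship
#' inverts.
#'
#' @param beta_p Length-7 vector or draws x 7 matrix.
#' @param scaling Optional standardization table with a snow row (mean
#'   and sd in meters; depths are then reported in cm). Alternatively
#'   give `snow_mean` and `snow_sd` directly, in the unit you want the
#'   depth reported in.
#' @param snow_mean,snow_sd Snow mean and sd on the reporting scale.
#' @param tol `|beta_3|` below which a draw is flagged as having no
#'   inversion.
#' @return A list with `depth` (posterior mean over draws with an
#'   inversion; `NA` if none), `summary` (tibble: mean, median, 90\%
#'   interval, fraction of draws without a physical inversion) and
#'   `draws` (per-draw depths, `NA` where undefined).
#' @export
snow_inversion_depth <- function(beta_p, scaling = NULL,
                                 snow_mean = NULL, snow_sd = NULL,
                                 tol = 1e-8) {
  if (!is.null(scaling)) {
    srow <- scaling[scaling$variable == "snow", ]
    if (nrow(srow) != 1) stop("scaling table lacks a snow row")
    snow_mean <- srow$mean * 100  # m -> cm
    snow_sd <- srow$sd * 100
  }
  if (is.null(snow_mean) || is.null(snow_sd)) {
    stop("provide either scaling or snow_mean and snow_sd")
  }
  if (!is.matrix(beta_p)) beta_p <- matrix(beta_p, nrow = 1)
  b1 <- beta_p[, 2]
  b3 <- beta_p[, 4]
  depth <- rep(NA_real_, length(b1))
  ok <- abs(b3) > tol
  depth[ok] <- snow_mean + snow_sd * (-b1[ok] / b3[ok])
  physical <- ok & depth >= 0
  no_inv <- mean(!physical)
  valid <- depth[physical]
  summary <- tibble::tibble(
    mean = if (length(valid)) mean(valid) else NA_real_,
    median = if (length(valid)) stats::median(valid) else NA_real_,
    lo90 = if (length(valid) >= 20) quantile(valid, 0.05, names = FALSE)
           else NA_real_,
    hi90 = if (length(valid) >= 20) quantile(valid, 0.95, names = FALSE)
           else NA_real_,
    frac_no_inversion = no_inv,
    n_draws = length(b1)
  )
  list(depth = summary$mean, summary = summary, draws = depth)
}
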