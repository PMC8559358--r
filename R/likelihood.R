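#' Log-likelihood of one movement step
#'
#' Bivariate normal density of fix `x_i` under the persistence process:
#' mean `x_prev + gamma * (dt/dt_prev) * (x_prev - x_prev2)`, covariance
#' `dt * sigma_x^2 * I`. Times are in hours, coordinates in km, so
#' `sigma_x` has units km per sqrt(hour).
#'
#' @param x,x_prev,x_prev2 Length-2 locations at times i, i-1, i-2.
#' @param gamma Persistence in (0, 1) (0 and 1 allowed as limits).
#' @param dt,dt_prev Time gaps `t_i - t_{i-1}` and `t_{i-1} - t_{i-2}`
#'   in hours; > 0.
#' @param sigma_x Process scale; > 0.
#' @return Log-density (scalar).
#' @export
step_loglik <- function(x, x_prev, x_prev2, gamma, dt, dt_prev, sigma_x) {
  vals <- c(x, x_prev, x_prev2, gamma, dt, dt_prev, sigma_x)
  if (any(!is.finite(vals))) stop("non-finite inputs to step_loglik")
  if (dt <= 0 || dt_prev <= 0) stop("time gaps must be positive")
  if (sigma_x <= 0) stop("sigma_x must be positive")
  mu <- x_prev + gamma * (dt / dt_prev) * (x_prev - x_prev2)
  sum(dnorm(x, mu, sqrt(dt) * sigma_x, log = TRUE))
}

#' Log-density of the latent logit-persistence
#'
#' Normal density of `eta_i = logit(gamma_i)` with mean `Z' beta` and
#' standard deviation `dt * sigma_nu` (variance `dt^2 sigma_nu^2`).
#'
#' @param eta Latent logit-persistence value.
#' @param z Length-7 design vector.
#' @param beta Length-7 coefficient vector.
#' @param dt Time gap in hours.
#' @param sigma_nu Latent scale; > 0.
#' @return Log-density (scalar).
#' @export
latent_loglik <- function(eta, z, beta, dt, sigma_nu) {
  if (any(!is.finite(c(eta, z, beta, dt, sigma_nu)))) {
    stop("non-finite inputs to latent_loglik")
  }
  if (sigma_nu <= 0) stop("sigma_nu must be positive")
  if (length(z) != 7 || length(beta) != 7) stop("z and beta must be length 7")
  dnorm(eta, sum(z * beta), dt * sigma_nu, log = TRUE)
}

#' Linear predictor of expected logit-persistence
#'
#' `E(logit gamma) = Z' beta`, optionally mapped through the inverse
#' logit to the persistence scale.
#'
#' @param Z Length-7 vector or n x 7 matrix / design tibble.
#' @param beta Length-7 coefficient vector.
#' @param inverse_link Return `plogis(Z' beta)` instead of the logit
#'   scale.
#' @return Numeric vector of linear predictors (or persistences).
#' @export
linear_predictor <- function(Z, beta, inverse_link = FALSE) {
  if (is.data.frame(Z)) Z <- as.matrix(Z)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != 7 || length(beta) != 7) {
    stop("Z must have 7 columns matching a length-7 beta")
  }
  eta <- drop(Z %*% beta)
  if (inverse_link) inv_logit(eta) else eta
}

#' Joint log-likelihood of a track and latent series
#'
#' Sum over steps i = 3..n of the movement-process density
#' ([step_loglik()]) and the latent-persistence density
#' ([latent_loglik()]), with `gamma_i = plogis(eta_i)`.
#'
#' @param track Tibble with `timestamp`, `x_km`, `y_km` (>= 3 fixes,
#'   strictly increasing times).
#' @param design Design tibble/matrix with one row per fix (rows 3..n
#'   are used).
#' @param eta Latent series of length `nrow(track) - 2` (for steps
#'   3..n).
#' @param beta Length-7 coefficients.
#' @param sigma_x,sigma_nu Process scales; > 0.
#' @return Scalar log-likelihood.
#' @export
total_loglik <- function(track, design, eta, beta, sigma_x, sigma_nu) {
  n <- nrow(track)
  stopifnot(n >= 3)
  Z <- as.matrix(design)
  if (nrow(Z) != n) stop("design must have one row per fix")
  if (length(eta) != n - 2) stop("eta must have length n - 2")
  dt <- diff(as.numeric(track$timestamp)) / 3600
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  xy <- cbind(track$x_km, track$y_km)
  ll <- 0
  for (i in 3:n) {
    s <- i - 2
    g <- inv_logit(eta[s])
    ll <- ll +
      step_loglik(xy[i, ], xy[i - 1, ], xy[i - 2, ], g,
                  dt[i - 1], dt[i - 2], sigma_x) +
      latent_loglik(eta[s], Z[i, ], beta, dt[i - 1], sigma_nu)
  }
  ll
}
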