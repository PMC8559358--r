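#' Stage-1 prior specification
#'
#' Independent priors for the individual-level model: each coefficient
#' `beta_k ~ Normal(0, beta_sd^2)` and half-Normal priors on the process
#' scales. The prior on beta is serialized with every fit because the
#' population stage's acceptance ratio divides by it.
#'
#' The latent scale sigma_nu is expressed per hour and multiplied by the
#' fix interval, so at an 8-h cadence a value of 0.6 already implies
#' step-to-step logit-persistence jumps with sd near 5 -- behaviorally
#' implausible churn. Its default prior scale (0.5) is therefore chosen
#' weakly informative on that natural scale; the movement scale sigma_x
#' is left diffuse (scale 5). A diffuse prior on sigma_nu also degrades
#' identifiability of the coefficients: the latent series can then chase
#' the flat tails of the per-step movement likelihood, which inflates
#' all logit-scale coefficients multiplicatively.
#'
#' @param beta_sd Prior sd of each coefficient (logit scale); wide
#'   relative to standardized covariates.
#' @param sigma_x_scale,sigma_nu_scale Half-Normal scales for the
#'   movement and latent process sds.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 2, sigma_x_scale = 5,
                       sigma_nu_scale = 0.5) {
  stopifnot(beta_sd > 0, sigma_x_scale > 0, sigma_nu_scale > 0)
  structure(list(beta_sd = beta_sd, sigma_x_scale = sigma_x_scale,
                 sigma_nu_scale = sigma_nu_scale), class = "prior_spec")
}

#' MCMC configuration
#'
#' Desk-scale defaults (3 chains of 5,000 iterations, half burn-in,
#' thinned by 10) keep routine fits to seconds; `paper_scale = TRUE`
#' switches to 3 chains of 100,000 iterations with 50,000 burn-in,
#' thinned by 10, for production runs.
#'
#' @param n_chains Number of chains (>= 1; >= 2 needed for R-hat).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param paper_scale Use the production-scale settings.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 5000,
                        n_burnin = floor(n_iter / 2), thin = 10,
                        paper_scale = FALSE) {
  if (paper_scale) {
    n_iter <- 100000; n_burnin <- 50000; thin <- 10
  }
  stopifnot(n_chains >= 1, n_iter > n_burnin, thin >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 n_burnin = n_burnin, thin = thin), class = "mcmc_config")
}

#' Fit the dynamic-persistence model to one individual-season
#'
#' Samples the joint posterior of the coefficients `beta` (7), the
#' process scales `sigma_x`, `sigma_nu` and the latent logit-persistence
#' series `eta_i` (steps i = 3..n) under the movement-process and
#' latent-regression densities with the priors of [prior_spec()]. The
#' sampler is an adaptive Metropolis-within-Gibbs scheme: `beta` is drawn
#' exactly from its conjugate conditional given `eta`; each `eta_i` and
#' the log-scales use adaptive random-walk Metropolis (adaptation frozen
#' after burn-in). Chains are initialized at `beta = 0` with per-chain
#' jitter, `eta = 0`, and method-of-moments process scales.
#'
#' @param track Tibble with `timestamp`, `x_km`, `y_km` (>= 3 fixes).
#' @param design Design tibble/matrix from [build_design_matrix()], one
#'   row per fix.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param seed Integer seed; fits are reproducible given the seed.
#' @param include_likelihood Internal switch used by prior-predictive
#'   checks; `FALSE` drops the movement-process density so the sampler
#'   targets the prior.
#' @return An object of class `persistence_fit` with elements `draws`
#'   (array draws x chains x 9 core parameters), `eta_draws` (array
#'   draws x chains x steps), `rhat` (tibble), `prior`, `config`,
#'   `track`, `design`, `seed`.
#' @export
fit_individual <- function(track, design, prior = prior_spec(),
                           config = mcmc_config(), seed = NULL,
                           include_likelihood = TRUE) {
  n <- nrow(track)
  if (n < 3) stop("need at least 3 fixes to fit the movement model")
  Z <- as.matrix(design)
  if (nrow(Z) != n || ncol(Z) != 7) {
    stop("design must be n x 7 with one row per fix")
  }
  ts <- as.numeric(track$timestamp)
  dt <- diff(ts) / 3600
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  xy <- cbind(track$x_km, track$y_km)
  if (any(!is.finite(xy))) stop("non-finite coordinates")
  m <- n - 2

  # method-of-moments initial scales from observed displacements
  disp2 <- rowSums((xy[-1, , drop = FALSE] -
                      xy[-n, , drop = FALSE])^2) / dt
  sx0 <- sqrt(max(mean(disp2) / 2, 1e-4))
  snu0 <- max(0.5 / mean(dt), 0.01)

  n_keep <- length(seq(config$n_burnin, config$n_iter - 1, by = config$thin))
  with_seed_if(seed, {
    chains <- purrr::map(seq_len(config$n_chains), function(ch) {
      beta0 <- rnorm(7, 0, 0.1)
      res <- dcrw_mcmc_chain(
        xy, dt, Z, prior$beta_sd, prior$sigma_x_scale,
        prior$sigma_nu_scale, beta0,
        sx0 * exp(rnorm(1, 0, 0.1)), snu0 * exp(rnorm(1, 0, 0.1)),
        config$n_iter, config$n_burnin, config$thin, include_likelihood)
      res
    })

    par_names <- c(paste0("beta_", mp_terms()), "sigma_x", "sigma_nu")
    draws <- array(NA_real_,
                   dim = c(n_keep, config$n_chains, 9),
                   dimnames = list(NULL, NULL, par_names))
    eta_draws <- array(NA_real_, dim = c(n_keep, config$n_chains, m))
    for (ch in seq_len(config$n_chains)) {
      draws[, ch, 1:7] <- chains[[ch]]$beta
      draws[, ch, 8] <- chains[[ch]]$sigma_x
      draws[, ch, 9] <- chains[[ch]]$sigma_nu
      eta_draws[, ch, ] <- chains[[ch]]$eta
    }

    rhat <- if (config$n_chains >= 2 && n_keep >= 4) {
      tibble::tibble(parameter = par_names,
                     rhat = as.numeric(compute_rhat(draws)))
    } else {
      tibble::tibble(parameter = par_names, rhat = NA_real_)
    }

    structure(
      list(draws = draws, eta_draws = eta_draws, rhat = rhat,
           prior = prior, config = config, seed = seed,
           track = track, design = design,
           scaling = attr(design, "covariate_scaling"),
           individual_id = if ("individual_id" %in% names(track))
             track$individual_id[1] else NA_character_),
      class = "persistence_fit"
    )
  })
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf(
    "<persistence_fit> %s: %d fixes, %d chains x %d kept draws, max R-hat %.3f\n",
    x$individual_id, nrow(x$track), dim(x$draws)[2],
    dim(x$draws)[1], max(x$rhat$rhat, na.rm = TRUE)))
  invisible(x)
}

# pooled draws (chains stacked) of the 9 core parameters
pooled_draws <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Posterior summary of the persistence series
#'
#' Per modeled step (i = 3..n): posterior mean of `gamma_i =
#' plogis(eta_i)` (mean of transformed draws, the reported quantity), a
#' 90\% equal-tailed interval, and the inverse logit of the posterior
#' mean `eta` (stored for reference; the two differ because the
#' transform is non-linear).
#'
#' @param fit A [fit_individual()] result.
#' @param level Credible level for the interval.
#' @return A tibble with `step`, `timestamp`, `gamma_mean`, `gamma_lo`,
#'   `gamma_hi`, `gamma_at_mean_eta`, and `gamma_true` when the track
#'   carries simulation truth.
#' @export
posterior_gamma <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "persistence_fit"))
  a <- (1 - level) / 2
  ed <- fit$eta_draws
  g <- inv_logit(ed)
  flat <- matrix(g, nrow = dim(g)[1] * dim(g)[2])
  eta_flat <- matrix(ed, nrow = dim(ed)[1] * dim(ed)[2])
  n <- nrow(fit$track)
  out <- tibble::tibble(
    step = 3:n,
    timestamp = fit$track$timestamp[3:n],
    gamma_mean = colMeans(flat),
    gamma_lo = apply(flat, 2, quantile, probs = a),
    gamma_hi = apply(flat, 2, quantile, probs = 1 - a),
    gamma_at_mean_eta = inv_logit(colMeans(eta_flat))
  )
  if ("gamma_true" %in% names(fit$track)) {
    out$gamma_true <- fit$track$gamma_true[3:n]
  }
  out
}
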