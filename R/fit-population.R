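#' Scale individual fits to the annual population level
#'
#' Second-stage recursive Bayesian MCMC. Each covariate k follows the
#' hierarchy `beta_jk ~ Normal(beta_pk, sigma_bk^2)`. Per sweep:
#' (a) each individual's `beta_jk` is updated by proposing a uniform draw
#' `beta*` from that individual's stage-1 posterior pool and accepting
#' with probability
#' `min(1, [N(beta* | beta_pk, sigma_bk) / g0(beta*)] /
#'          [N(beta_jk | beta_pk, sigma_bk) / g0(beta_jk)])`
#' where `g0` is the stage-1 prior density -- the stage-1 likelihood
#' cancels because the proposal is the stage-1 posterior;
#' (b) `beta_pk` is drawn from its conjugate normal conditional under the
#' informative `Normal(0, tau^2)` hyperprior; (c) `sigma_bk^2` from its
#' conjugate inverse-gamma conditional.
#'
#' @param fits List of [fit_individual()] results (>= 2), or a list of
#'   lists with elements `beta` (draws x 7 matrix) and `prior_beta_sd`.
#' @param tau Hyperprior sd of each `beta_pk` (informative, centered on
#'   zero).
#' @param sigma_shape,sigma_rate Inverse-gamma hyperprior on
#'   `sigma_bk^2`.
#' @param n_iter,n_burnin Second-stage iterations and burn-in.
#' @param sigma_beta_fixed Optional length-7 vector fixing
#'   `sigma_bk` (skips step c); used e.g. to compare against the
#'   closed-form normal-normal update.
#' @param seed Integer seed.
#' @param year Optional label stored with the result.
#' @return An object of class `population_fit` with draw matrices
#'   `beta_p` and `sigma_beta` (iterations x 7), acceptance rates, and
#'   the configuration.
#' @export
fit_population <- function(fits, tau = 1, sigma_shape = 2, sigma_rate = 1,
                           n_iter = 4000, n_burnin = 1000,
                           sigma_beta_fixed = NULL, seed = NULL,
                           year = NA) {
  if (length(fits) < 2) stop("need at least 2 individual fits")
  pools <- purrr::map(fits, function(f) {
    if (inherits(f, "persistence_fit")) {
      list(beta = pooled_draws(f)[, 1:7, drop = FALSE],
           prior_beta_sd = f$prior$beta_sd)
    } else {
      if (is.null(f$beta) || is.null(f$prior_beta_sd)) {
        stop("each fit must carry beta draws and its stage-1 prior")
      }
      list(beta = as.matrix(f$beta), prior_beta_sd = f$prior_beta_sd)
    }
  })
  J <- length(pools)
  K <- 7
  ids <- purrr::map_chr(seq_along(fits), function(j) {
    f <- fits[[j]]
    if (inherits(f, "persistence_fit") && !is.na(f$individual_id))
      f$individual_id else paste0("ind", j)
  })

  with_seed_if(seed, {
    beta_j <- vapply(pools, function(p) colMeans(p$beta), numeric(K))
    beta_j <- t(beta_j)  # J x K
    beta_p <- colMeans(beta_j)
    sig2 <- pmax(apply(beta_j, 2, var), 1e-4)
    if (!is.null(sigma_beta_fixed)) {
      stopifnot(length(sigma_beta_fixed) == K, all(sigma_beta_fixed > 0))
      sig2 <- sigma_beta_fixed^2
    }

    keep <- n_iter - n_burnin
    out_bp <- matrix(NA_real_, keep, K,
                     dimnames = list(NULL, mp_terms()))
    out_sb <- matrix(NA_real_, keep, K,
                     dimnames = list(NULL, mp_terms()))
    acc <- matrix(0, J, K)

    for (it in seq_len(n_iter)) {
      for (k in seq_len(K)) {
        sb <- sqrt(sig2[k])
        # (a) refresh individual coefficients from stage-1 pools
        for (j in seq_len(J)) {
          pool <- pools[[j]]$beta[, k]
          g0sd <- pools[[j]]$prior_beta_sd
          star <- pool[sample.int(length(pool), 1)]
          cur <- beta_j[j, k]
          logr <- dnorm(star, beta_p[k], sb, log = TRUE) -
            dnorm(star, 0, g0sd, log = TRUE) -
            dnorm(cur, beta_p[k], sb, log = TRUE) +
            dnorm(cur, 0, g0sd, log = TRUE)
          if (log(runif(1)) < logr) {
            beta_j[j, k] <- star
            acc[j, k] <- acc[j, k] + 1
          }
        }
        # (b) conjugate update of beta_p under N(0, tau^2) hyperprior
        prec <- J / sig2[k] + 1 / tau^2
        mu <- (sum(beta_j[, k]) / sig2[k]) / prec
        beta_p[k] <- rnorm(1, mu, sqrt(1 / prec))
        # (c) conjugate inverse-gamma update of sigma_bk^2
        if (is.null(sigma_beta_fixed)) {
          shape <- sigma_shape + J / 2
          rate <- sigma_rate + sum((beta_j[, k] - beta_p[k])^2) / 2
          sig2[k] <- 1 / stats::rgamma(1, shape, rate = rate)
        }
      }
      if (it > n_burnin) {
        out_bp[it - n_burnin, ] <- beta_p
        out_sb[it - n_burnin, ] <- sqrt(sig2)
      }
    }

    acc_rate <- acc / n_iter
    if (any(colSums(acc) == 0)) {
      stop("zero acceptance for covariate(s) ",
           paste(mp_terms()[colSums(acc) == 0], collapse = ", "),
           "; stage-1 pools may be degenerate or incompatible")
    }

    structure(
      list(beta_p = out_bp, sigma_beta = out_sb,
           acceptance = acc_rate, individuals = ids,
           tau = tau, sigma_shape = sigma_shape, sigma_rate = sigma_rate,
           sigma_beta_fixed = sigma_beta_fixed,
           n_iter = n_iter, n_burnin = n_burnin, seed = seed, year = year),
      class = "population_fit"
    )
  })
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf(
    "<population_fit> %d individuals, %d kept draws%s\n",
    length(x$individuals), nrow(x$beta_p),
    if (is.na(x$year)) "" else paste0(" (year ", x$year, ")")))
  invisible(x)
}

#' Equal-tailed credible interval
#'
#' @param draws Numeric vector of posterior draws (>= 20).
#' @param level Credible level (default 0.90).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(draws, level = 0.90) {
  if (length(draws) < 20) stop("need at least 20 draws")
  a <- (1 - level) / 2
  q <- quantile(draws, c(a, 1 - a), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Classify covariate effects across years
#'
#' Applies the reporting rule for population-level effects: a
#' covariate-year shows an effect when its 90\% credible interval
#' excludes zero; a covariate shows a consistent effect when at least two
#' years exclude zero with a common sign.
#'
#' @param ci_table Tibble with columns `year`, `term`, `lo`, `hi` (one
#'   row per covariate-year).
#' @return A list with `by_year` (adds `sign`, `excludes_zero`) and
#'   `by_term` (per covariate: counts of years excluding zero by sign
#'   and the `consistent_effect` flag with its direction).
#' @export
classify_effects <- function(ci_table) {
  stopifnot(all(c("year", "term", "lo", "hi") %in% names(ci_table)),
            nrow(ci_table) >= 1)
  by_year <- ci_table |>
    dplyr::mutate(
      excludes_zero = .data$lo > 0 | .data$hi < 0,
      sign = dplyr::case_when(.data$lo > 0 ~ "positive",
                              .data$hi < 0 ~ "negative",
                              TRUE ~ "none")
    )
  by_term <- by_year |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      n_positive = sum(.data$sign == "positive"),
      n_negative = sum(.data$sign == "negative"),
      n_excluding_zero = sum(.data$excludes_zero),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      consistent_effect = pmax(.data$n_positive, .data$n_negative) >= 2,
      direction = dplyr::case_when(
        .data$consistent_effect &
          .data$n_positive >= .data$n_negative ~ "positive",
        .data$consistent_effect ~ "negative",
        TRUE ~ NA_character_
      )
    )
  list(by_year = by_year, by_term = by_term)
}
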