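#' Rank-normalized split R-hat
#'
#' Potential scale reduction statistic computed on rank-normalized draws
#' after splitting each chain in half, the modern convergence diagnostic
#' robust to heavy tails and trends within chains. Values near 1 indicate
#' the chains sample the same distribution; the conventional convergence
#' bound for reporting is 1.01.
#'
#' @param draws A draws-by-chains numeric matrix, or a 3-d array
#'   (draws, chains, parameters), in which case a named vector of R-hat
#'   values is returned.
#' @return Scalar R-hat (matrix input) or named numeric vector (array
#'   input). Parameters with zero variance return `NA`.
#' @export
compute_rhat <- function(draws) {
  if (is.array(draws) && length(dim(draws)) == 3) {
    out <- apply(draws, 3, compute_rhat)
    return(out)
  }
  draws <- as.matrix(draws)
  n <- nrow(draws)
  n_chains <- ncol(draws)
  if (n_chains < 2) stop("R-hat requires at least 2 chains")
  if (n < 4) stop("R-hat requires at least 4 draws per chain")
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  if (stats::sd(as.vector(split)) == 0) return(NA_real_)
  S <- length(split)
  z <- qnorm((rank(split, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  z <- matrix(z, nrow = half)
  rhat_classic(z)
}

# classic split-free R-hat on a draws x chains matrix
rhat_classic <- function(x) {
  n <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}
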