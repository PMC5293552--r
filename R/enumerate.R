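#' Exact spike-and-slab posterior by exhaustive enumeration
#'
#' For small numbers of candidate regressors, the spike-and-slab linear
#' model with known Gaussian noise is exactly tractable: for each of the
#' `2^p` inclusion configurations the evidence is a closed-form Gaussian
#' integral, and posterior inclusion probabilities and weight means follow
#' by Bayes weighting. Used as the independent exact reference for the
#' approximate (message-passing) solver on small problems; infeasible beyond
#' a handful of regressors.
#'
#' Model: `y ~ N(X w, noise_var * I)`; selected columns carry the
#' spike-and-slab prior, columns listed in `gauss_idx` carry a plain
#' Gaussian prior `N(gauss_mean, gauss_var)` and are always included.
#'
#' @param X Design matrix (rows = observations).
#' @param y Response vector.
#' @param noise_var Known Gaussian noise variance.
#' @param rho Prior inclusion probability per spike-and-slab column
#'   (recycled to their number).
#' @param slab_var,spike_var Mixture component variances.
#' @param gauss_idx Optional column indices with plain Gaussian priors.
#' @param gauss_mean,gauss_var Prior mean/variance for those columns
#'   (recycled).
#' @return List with `inclusion` and `mean` vectors (length `ncol(X)`;
#'   inclusion is `NA` for Gaussian-prior columns), `log_evidence`, and a
#'   tibble `configs` of per-configuration posterior weights.
#' @export
enumerate_spike_slab <- function(X, y, noise_var, rho,
                                 slab_var = 10, spike_var = 1e-4,
                                 gauss_idx = integer(0),
                                 gauss_mean = 0, gauss_var = 10) {
  P <- ncol(X)
  sel <- setdiff(seq_len(P), gauss_idx)
  p <- length(sel)
  if (p > 15) abort("Exhaustive enumeration is limited to 15 spike-and-slab columns.")
  rho <- rep_len(rho, p)
  gauss_mean <- rep_len(gauss_mean, length(gauss_idx))
  gauss_var <- rep_len(gauss_var, length(gauss_idx))
  nr <- nrow(X)

  m0 <- numeric(P); m0[gauss_idx] <- gauss_mean
  base_v <- numeric(P); base_v[gauss_idx] <- gauss_var

  configs <- as.matrix(expand.grid(rep(list(c(0, 1)), p)))
  log_w <- numeric(nrow(configs))
  means <- matrix(0, nrow(configs), P)
  for (k in seq_len(nrow(configs))) {
    g <- configs[k, ]
    v <- base_v
    v[sel] <- ifelse(g == 1, slab_var, spike_var)
    # evidence: y ~ N(X m0, X V X' + noise_var I)
    K <- X %*% (v * t(X)) + diag(noise_var, nr)
    ch <- chol(K)
    resid <- y - drop(X %*% m0)
    alpha <- backsolve(ch, backsolve(ch, resid, transpose = TRUE))
    log_lik <- -0.5 * (nr * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(resid * alpha))
    log_prior <- sum(ifelse(g == 1, log(rho), log1p(-rho)))
    log_w[k] <- log_lik + log_prior
    means[k, ] <- m0 + v * drop(t(X) %*% alpha)
  }
  w <- exp(log_w - log_sum_exp(log_w))
  inclusion <- rep(NA_real_, P)
  inclusion[sel] <- drop(t(configs) %*% w)
  list(inclusion = inclusion,
       mean = drop(t(means) %*% w),
       log_evidence = log_sum_exp(log_w),
       configs = tibble::tibble(config = apply(configs, 1, paste, collapse = ""),
                                weight = w, log_joint = log_w))
}
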