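#' Exact moments of a Gaussian cavity times a spike-and-slab factor
#'
#' The one-dimensional hybrid `N(w | cavity_mean, cavity_var) *
#' [rho N(w | 0, slab_var) + (1 - rho) N(w | 0, spike_var)]` is a
#' two-component Gaussian mixture whose normalizer, first two moments and
#' slab responsibility are available in closed form. The responsibility is
#' the updated inclusion probability of the edge.
#'
#' @param cavity_mean,cavity_var Cavity (leave-one-out posterior) moments;
#'   `cavity_var` must be positive (a non-positive value signals a numerical
#'   failure upstream in the message-passing loop).
#' @param rho Prior inclusion probability of this weight.
#' @param slab_var,spike_var Mixture component variances.
#' @return List with `mean`, `var`, `inclusion`, `log_norm`.
#' @export
spike_slab_site_moments <- function(cavity_mean, cavity_var, rho,
                                    slab_var = 10, spike_var = 1e-4) {
  if (!is.finite(cavity_var) || cavity_var <= 0) {
    abort("Non-positive cavity variance: EP numerical failure upstream.")
  }
  vs <- c(slab_var, spike_var)
  logZ <- dnorm(cavity_mean, 0, sqrt(cavity_var + vs), log = TRUE)
  logw <- c(log(rho), log1p(-rho)) + logZ
  log_norm <- log_sum_exp(logw)
  w <- exp(logw - log_norm)
  mk <- cavity_mean * vs / (cavity_var + vs)
  vk <- cavity_var * vs / (cavity_var + vs)
  mean <- sum(w * mk)
  var <- sum(w * (vk + mk^2)) - mean^2
  list(mean = mean, var = var, inclusion = w[1], log_norm = log_norm)
}

# Gaussian-cavity integral of an unnormalized Gaussian site exp(r w - q w^2 / 2)
log_int_cavity_site <- function(m, v, q, r) {
  -0.5 * log1p(q * v) + (m / v + r)^2 * v / (2 * (1 + q * v)) - m^2 / (2 * v)
}

#' Moment-match one likelihood site by quadrature
#'
#' Under the Student-t marginal observation model the likelihood factor of
#' one observation row is not Gaussian in the weights. Its EP update reduces
#' to a one-dimensional problem on the scalar projection `u = row . w`: the
#' tilted density `N(u | cavity) * St(y | mu(u), a, b)` is integrated
#' numerically, where `mu(u) = u` in linear mode and `mu(u)` is clamped to
#' the row's measurement bounds in clipped mode.
#'
#' @param y Observed response of the row.
#' @param cavity_mean,cavity_var Cavity moments of the projection `u`.
#' @param noise A [noise_model] (hyperparameters of the Student-t).
#' @param response `"linear"` or `"clipped"`.
#' @param lower,upper Row bounds for clipped mode.
#' @return List with `mean`, `var`, `log_norm` of the tilted distribution of
#'   `u`, or `NULL` when the quadrature failed to produce finite moments
#'   (the caller skips the site for this sweep).
#' @export
likelihood_site_update <- function(y, cavity_mean, cavity_var, noise,
                                   response = c("linear", "clipped"),
                                   lower = -Inf, upper = Inf) {
  response <- match.arg(response)
  if (!is.finite(cavity_var) || cavity_var <= 0) {
    abort("Non-positive cavity variance: EP numerical failure upstream.")
  }
  s <- sqrt(cavity_var)
  grid <- cavity_mean + s * seq(-8, 8, length.out = 401)
  mu <- if (response == "clipped") pmin(pmax(grid, lower), upper) else grid
  logf <- dnorm(grid, cavity_mean, s, log = TRUE) +
    student_t_marginal_density(y, mu, noise$a, noise$b, log = TRUE)
  m <- max(logf)
  f <- exp(logf - m)
  h <- grid[2] - grid[1]
  z0 <- sum(f) * h
  if (!is.finite(z0) || z0 <= 0) return(NULL)
  m1 <- sum(f * grid) * h / z0
  m2 <- sum(f * grid^2) * h / z0
  v <- m2 - m1^2
  if (!is.finite(m1) || !is.finite(v) || v <= 0) return(NULL)
  list(mean = m1, var = v, log_norm = m + log(z0))
}

#' Expectation-propagation solver for spike-and-slab regression
#'
#' The workhorse behind per-node network inference: Bayesian linear
#' regression `y = X w + e` where selected columns carry a spike-and-slab
#' prior (yielding posterior inclusion probabilities) and the remaining
#' columns (decay, intercept) carry plain Gaussian priors.
#'
#' Two noise modes. In `"gaussian"` mode the noise variance is known
#' (`noise_var`) and the likelihood factor is exactly Gaussian, so EP
#' iterates only over the non-Gaussian prior sites, each updated in closed
#' form via [spike_slab_site_moments]. In `"student_t"` mode the per-row
#' Student-t marginal likelihood (noise variance integrated out) is
#' approximated by per-row Gaussian sites refined by one-dimensional
#' quadrature ([likelihood_site_update]); the prior sites are refreshed
#' after each full data sweep.
#'
#' Site updates are damped and the global covariance is kept positive
#' definite by step-halving; a site whose update would destroy positive
#' definiteness (or whose quadrature fails) is skipped for that sweep.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param rho Prior inclusion probability per column; `NA` marks
#'   Gaussian-prior columns.
#' @param noise_var Known noise variance (gaussian mode).
#' @param slab_var,spike_var Spike-and-slab component variances.
#' @param gauss_mean,gauss_var Prior moments for `NA`-rho columns (recycled).
#' @param max_iters Maximum number of sweeps (0 returns the prior exactly).
#' @param tol Convergence tolerance on the maximum absolute change of
#'   posterior means and inclusion probabilities per sweep.
#' @param damping Damping factor in (0, 1]: fraction of the new site
#'   parameters used.
#' @param order `"fixed"` (default) or `"random"` site-update order.
#' @param seed Only used when `order = "random"`.
#' @param noise_mode `"gaussian"` or `"student_t"`.
#' @param noise A [noise_model] for `"student_t"` mode.
#' @param response `"linear"` or `"clipped"` (student_t mode only).
#' @param lower,upper Per-row bounds for clipped mode (recycled).
#' @param min_var Variance floor for site moment matching.
#' @return List of class `ep_fit` with posterior `mean`, `sd`, `inclusion`
#'   per column, `log_evidence`, `iterations`, `converged`, `failed`,
#'   `n_skipped`.
#' @export
ep_spike_slab <- function(X, y, rho, noise_var = NULL,
                          slab_var = 10, spike_var = 1e-4,
                          gauss_mean = 0, gauss_var = 10,
                          max_iters = 20, tol = 1e-4, damping = 0.8,
                          order = c("fixed", "random"), seed = NULL,
                          noise_mode = c("gaussian", "student_t"),
                          noise = noise_model(),
                          response = c("linear", "clipped"),
                          lower = -Inf, upper = Inf,
                          min_var = 1e-10) {
  order <- match.arg(order)
  noise_mode <- match.arg(noise_mode)
  response <- match.arg(response)
  if (max_iters < 0 || damping <= 0 || damping > 1) {
    abort("Need max_iters >= 0 and 0 < damping <= 1.")
  }
  X <- as.matrix(X)
  P <- ncol(X); nr <- nrow(X)
  rho <- rep_len(rho, P)
  sel <- which(!is.na(rho))
  gidx <- which(is.na(rho))
  gm <- rep_len(gauss_mean, length(gidx))
  gv <- rep_len(gauss_var, length(gidx))
  lower <- rep_len(lower, nr); upper <- rep_len(upper, nr)

  prior_var0 <- rho[sel] * slab_var + (1 - rho[sel]) * spike_var

  prior_only <- function(failed) {
    mean <- numeric(P); sd <- sqrt(rep(0, P))
    mean[gidx] <- gm
    sd <- numeric(P); sd[gidx] <- sqrt(gv)
    sd[sel] <- sqrt(prior_var0)
    incl <- rep(NA_real_, P); incl[sel] <- rho[sel]
    structure(list(mean = mean, sd = sd, inclusion = incl,
                   log_evidence = NA_real_, iterations = 0L,
                   converged = !failed, failed = failed, n_skipped = 0L),
              class = "ep_fit")
  }
  if (max_iters == 0) return(prior_only(failed = FALSE))

  # exact Gaussian part of the posterior: likelihood (gaussian mode) and
  # plain-Gaussian prior columns
  Qd <- matrix(0, P, P)
  rd <- numeric(P)
  if (noise_mode == "gaussian") {
    if (is.null(noise_var) || noise_var <= 0) abort("gaussian mode needs a positive `noise_var`.")
    Qd <- crossprod(X) / noise_var
    rd <- drop(crossprod(X, y)) / noise_var
  }
  if (length(gidx)) {
    Qd[cbind(gidx, gidx)] <- Qd[cbind(gidx, gidx)] + 1 / gv
    rd[gidx] <- rd[gidx] + gm / gv
  }

  # site natural parameters: one per spike-and-slab prior factor, and in
  # student_t mode one per observation row (rank-one in the row direction)
  q_site <- numeric(P); r_site <- numeric(P)
  q_site[sel] <- 1 / prior_var0
  incl <- rep(NA_real_, P); incl[sel] <- rho[sel]
  lq_site <- numeric(nr); lr_site <- numeric(nr)   # likelihood sites on u = x.w
  llog_norm <- numeric(nr)
  plog_norm <- numeric(P)

  # likelihood sites start at zero, so the initial precision is exact + prior
  Sigma <- tryCatch(chol2inv(chol(Qd + diag(q_site, P))), error = function(e) NULL)
  if (is.null(Sigma)) return(prior_only(failed = TRUE))
  rvec <- rd + r_site + if (noise_mode == "student_t") drop(crossprod(X, lr_site)) else 0
  h <- drop(Sigma %*% rvec)

  n_skipped <- 0L
  converged <- FALSE
  iter <- 0L
  if (order == "random" && !is.null(seed)) {
    runif(1)  # ensure RNG initialized
    old_seed <- .Random.seed
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  for (iter in seq_len(max_iters)) {
    h_old <- h; incl_old <- incl

    if (noise_mode == "student_t") {
      for (i in seq_len(nr)) {
        xr <- X[i, ]
        sx <- drop(Sigma %*% xr)
        vu <- sum(xr * sx)
        mu <- sum(xr * h)
        qc <- 1 / vu - lq_site[i]
        if (!is.finite(qc) || qc <= 1e-12) { n_skipped <- n_skipped + 1L; next }
        vc <- 1 / qc
        mc <- (mu / vu - lr_site[i]) * vc
        mom <- likelihood_site_update(y[i], mc, vc, noise, response,
                                      lower[i], upper[i])
        if (is.null(mom)) { n_skipped <- n_skipped + 1L; next }
        v_new <- max(mom$var, min_var)
        q_t <- 1 / v_new - qc
        r_t <- mom$mean / v_new - mc / vc
        dq <- damping * (q_t - lq_site[i])
        dr <- damping * (r_t - lr_site[i])
        ok <- FALSE
        for (half in 1:30) {
          if (1 + dq * vu > 1e-10) { ok <- TRUE; break }
          dq <- dq / 2; dr <- dr / 2
        }
        if (!ok) { n_skipped <- n_skipped + 1L; next }
        Sigma <- Sigma - (dq / (1 + dq * vu)) * tcrossprod(sx)
        lq_site[i] <- lq_site[i] + dq
        lr_site[i] <- lr_site[i] + dr
        rvec <- rvec + dr * xr
        h <- drop(Sigma %*% rvec)
        llog_norm[i] <- mom$log_norm - log_int_cavity_site(mc, vc, lq_site[i], lr_site[i])
      }
    }

    idx <- if (order == "random") sample(sel) else sel
    for (j in idx) {
      v <- Sigma[j, j]
      m <- h[j]
      qc <- 1 / v - q_site[j]
      if (!is.finite(qc) || qc <= 1e-12) { n_skipped <- n_skipped + 1L; next }
      vc <- 1 / qc
      mc <- (m / v - r_site[j]) * vc
      mom <- spike_slab_site_moments(mc, vc, rho[j], slab_var, spike_var)
      v_new <- max(mom$var, min_var)
      q_t <- 1 / v_new - qc
      r_t <- mom$mean / v_new - mc / vc
      dq <- damping * (q_t - q_site[j])
      dr <- damping * (r_t - r_site[j])
      ok <- FALSE
      for (half in 1:30) {
        if (1 + dq * v > 1e-10) { ok <- TRUE; break }
        dq <- dq / 2; dr <- dr / 2
      }
      if (!ok) { n_skipped <- n_skipped + 1L; next }
      sj <- Sigma[, j]
      Sigma <- Sigma - (dq / (1 + dq * v)) * tcrossprod(sj)
      q_site[j] <- q_site[j] + dq
      r_site[j] <- r_site[j] + dr
      rvec[j] <- rvec[j] + dr
      h <- drop(Sigma %*% rvec)
      incl[j] <- mom$inclusion
      plog_norm[j] <- mom$log_norm - log_int_cavity_site(mc, vc, q_site[j], r_site[j])
    }

    delta <- max(c(abs(h - h_old), abs(incl[sel] - incl_old[sel]), 0), na.rm = TRUE)
    if (is.finite(delta) && delta < tol) { converged <- TRUE; break }
  }

  if (any(!is.finite(h)) || any(diag(Sigma) <= 0)) {
    return(prior_only(failed = TRUE))
  }

  # EP approximation of the log evidence: Gaussian integral of the exact
  # factors times all sites, corrected by the per-site tilted normalizers
  Q <- Qd + diag(q_site, P)
  if (noise_mode == "student_t") {
    for (i in seq_len(nr)) Q <- Q + lq_site[i] * tcrossprod(X[i, ])
  }
  log_evidence <- tryCatch({
    ch <- chol(Q)
    const <- 0
    if (noise_mode == "gaussian") {
      const <- const - nr / 2 * log(2 * pi * noise_var) - sum(y^2) / (2 * noise_var)
    }
    if (length(gidx)) {
      const <- const - sum(0.5 * log(2 * pi * gv) + gm^2 / (2 * gv))
    }
    const + P / 2 * log(2 * pi) - sum(log(diag(ch))) + 0.5 * sum(rvec * h) +
      sum(plog_norm[sel]) + if (noise_mode == "student_t") sum(llog_norm) else 0
  }, error = function(e) NA_real_)

  structure(list(mean = h, sd = sqrt(pmax(diag(Sigma), 0)), inclusion = incl,
                 log_evidence = log_evidence, iterations = iter,
                 converged = converged, failed = FALSE,
                 n_skipped = n_skipped),
            class = "ep_fit")
}
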