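#' Network model
#'
#' Parameterizes the generative model: a weighted directed graph over
#' `n` molecules plus `m` perturbation nodes, with per-molecule decay
#' `alpha` (1/time) and production `beta` (concentration/time). Entry
#' `W[p, i]` is the weight of edge p -> i. Structural zeros: the diagonal
#' (self-regulation is carried by `alpha`) and every column of a
#' perturbation node (no edges into perturbation nodes).
#'
#' The dynamics of molecule i are
#' `dy_i/dt = beta_i * g(sum_{p != i} w_pi z_p(t)) - alpha_i * y_i(t)`
#' with `g` the logistic sigmoid and `z` the joint state of molecules and
#' perturbation signals.
#'
#' @param W Square numeric matrix, `(n+m) x (n+m)`, indexed source x target.
#' @param alpha,beta Positive numeric vectors of length `n`.
#' @param molecules,perturbations Node names; together they must label the
#'   rows/columns of `W` in order.
#' @return An object of class `network_model`.
#' @export
network_model <- function(W, alpha, beta, molecules, perturbations = character(0)) {
  nodes <- c(molecules, perturbations)
  n <- length(molecules); m <- length(perturbations)
  if (!is.matrix(W) || nrow(W) != n + m || ncol(W) != n + m) {
    abort(sprintf("`W` must be a %d x %d matrix (molecules + perturbations).", n + m, n + m))
  }
  dimnames(W) <- list(nodes, nodes)
  if (any(diag(W)[seq_len(n)] != 0)) {
    abort("Diagonal entries for molecules must be zero (decay is carried by alpha).")
  }
  if (m > 0 && any(W[, n + seq_len(m)] != 0)) {
    abort("Edges into perturbation nodes are not representable; their columns must be zero.")
  }
  if (length(alpha) != n || length(beta) != n || any(alpha <= 0) || any(beta <= 0)) {
    abort("`alpha` and `beta` must be positive and of length n (one per molecule).")
  }
  structure(list(W = W, alpha = alpha, beta = beta,
                 molecules = molecules, perturbations = perturbations),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  n <- length(x$molecules); m <- length(x$perturbations)
  cat(sprintf("<network_model: %d molecules, %d perturbation nodes, %d edges>\n",
              n, m, sum(x$W != 0)))
  invisible(x)
}

#' Inverse-gamma noise hyperparameters
#'
#' The measurement-noise variance of each molecule is treated as unknown and
#' integrated out against an inverse-gamma prior IG(a, b), which turns the
#' Gaussian observation density into a Student-t. Defaults are weakly
#' informative at DREAM-like concentration scales.
#'
#' @param a Shape, dimensionless, > 0.
#' @param b Scale, squared concentration units, > 0.
#' @export
noise_model <- function(a = 1, b = 0.1) {
  if (any(a <= 0) || any(b <= 0)) abort("Noise hyperparameters `a` and `b` must be positive.")
  structure(list(a = a, b = b), class = "noise_model")
}

#' Total regulatory input of a node
#'
#' Dot product of a weight column with the joint state vector:
#' `sum_p w_p z_p`. The caller is responsible for excluding the node's own
#' entry (structurally zero in a [network_model]).
#'
#' @param w Weight vector (one column of W).
#' @param z State vector of the same length.
#' @export
regulator_input <- function(w, z) {
  if (length(w) != length(z)) {
    abort(sprintf("Weight column has length %d but state vector has length %d.",
                  length(w), length(z)))
  }
  sum(w * z)
}

#' Sigmoidal response
#'
#' `1 / (1 + exp(-u))`, numerically stable for large |u|.
#'
#' @param u Numeric vector.
#' @export
sigmoid_response <- function(u) plogis(u)

#' Piecewise-linear (clipped) response
#'
#' The bounded surrogate for the sigmoid: identity between `lower` and
#' `upper`, saturating at the bounds. The bounds are the minimally and
#' maximally measured concentrations of the molecule in that replicate and
#' condition, computed from data only ([compute_clip_bounds]).
#'
#' @param u Numeric vector.
#' @param lower,upper Clip bounds, `lower <= upper`.
#' @export
clipped_response <- function(u, lower, upper) {
  if (any(lower > upper)) abort("Clip bounds must satisfy lower <= upper.")
  pmin(pmax(u, lower), upper)
}

response_fun <- function(response = c("sigmoid", "clipped"), lower = -Inf, upper = Inf) {
  response <- match.arg(response)
  if (response == "sigmoid") sigmoid_response else function(u) clipped_response(u, lower, upper)
}

#' One Euler step of the discretized dynamics
#'
#' `mu = dt * beta * g(u) + y_t * (1 - alpha * dt)`: the model-implied mean of
#' the next measurement given the current state and total regulatory input.
#' `dt` weights the influence of the current measurement on the next one;
#' grids may be irregular.
#'
#' @param y_t Current value.
#' @param u_t Total regulatory input at the current time.
#' @param alpha,beta Decay and production parameters.
#' @param dt Positive time-interval length.
#' @param response `"sigmoid"` or `"clipped"`.
#' @param lower,upper Clip bounds for the clipped response.
#' @export
discrete_step <- function(y_t, u_t, alpha, beta, dt,
                          response = c("sigmoid", "clipped"),
                          lower = -Inf, upper = Inf) {
  if (any(dt <= 0)) abort("`dt` must be positive.")
  if (any(alpha * dt >= 1)) {
    warn("alpha * dt >= 1: the Euler scheme can oscillate on this grid.")
  }
  g <- response_fun(response, lower, upper)
  dt * beta * g(u_t) + y_t * (1 - alpha * dt)
}

#' Steady-state response
#'
#' Fixed point of the dynamics at dy/dt = 0: `(beta / alpha) * g(u)`.
#'
#' @inheritParams discrete_step
#' @param u Total regulatory input.
#' @export
steady_state_response <- function(u, alpha, beta,
                                  response = c("sigmoid", "clipped"),
                                  lower = -Inf, upper = Inf) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  g <- response_fun(response, lower, upper)
  (beta / alpha) * g(u)
}

#' Student-t marginal observation density
#'
#' Gaussian observation density with the noise variance integrated out
#' against IG(a, b):
#' `Gamma(a + 1/2) / Gamma(a) * (2 pi b)^(-1/2) * (1 + (mu - y)^2 / (2 b))^-(a + 1/2)`.
#' A scaled Student-t with 2a degrees of freedom; integrates to 1 over `y`.
#'
#' @param y Observed next value.
#' @param mu Model-implied mean.
#' @param a,b Inverse-gamma hyperparameters, both > 0.
#' @param log Return the log-density?
#' @export
student_t_marginal_density <- function(y, mu, a, b, log = FALSE) {
  if (any(a <= 0) || any(b <= 0)) abort("`a` and `b` must be positive.")
  ld <- lgamma(a + 0.5) - lgamma(a) - 0.5 * log(2 * pi * b) -
    (a + 0.5) * log1p((mu - y)^2 / (2 * b))
  if (log) ld else exp(ld)
}

#' Log marginal likelihood of a dataset under a network model
#'
#' Sums the log Student-t marginal density over all conditions, replicates,
#' molecules and time transitions (time-series mode) or single steady-state
#' observations (steady-state mode). The model-implied mean comes from
#' [discrete_step] or [steady_state_response]; missing values contribute
#' nothing.
#'
#' @param dataset A [pert_dataset] whose molecule set matches `model`.
#' @param model A [network_model].
#' @param noise A [noise_model].
#' @param response `"sigmoid"` or `"clipped"`; the clipped response uses
#'   per-series bounds from [compute_clip_bounds].
#' @export
log_marginal_likelihood <- function(dataset, model, noise = noise_model(),
                                    response = c("sigmoid", "clipped")) {
  response <- match.arg(response)
  if (!length(dataset$blocks)) abort("Empty dataset.")
  if (!identical(dataset$molecules, model$molecules)) {
    abort("Dataset and model molecule sets differ.")
  }
  n <- n_molecules(dataset)
  bounds <- if (response == "clipped") compute_clip_bounds(dataset) else NULL
  total <- 0
  for (b in dataset$blocks) {
    z <- block_z(b)
    lo <- rep(-Inf, n); hi <- rep(Inf, n)
    if (!is.null(bounds)) {
      bb <- bounds[bounds$condition == b$condition & bounds$replicate == b$replicate, ]
      lo[match(bb$molecule, dataset$molecules)] <- bb$lower
      hi[match(bb$molecule, dataset$molecules)] <- bb$upper
    }
    if (dataset$mode == "steadystate") {
      u <- drop(z[1, , drop = FALSE] %*% model$W)[seq_len(n)]
      for (i in seq_len(n)) {
        y <- b$y[1, i]
        if (is.na(y) || is.na(u[i])) next
        mu <- steady_state_response(u[i], model$alpha[i], model$beta[i],
                                    response, lo[i], hi[i])
        total <- total + student_t_marginal_density(y, mu, noise$a, noise$b, log = TRUE)
      }
    } else {
      tn <- length(b$times)
      if (tn < 2) next
      for (tt in seq_len(tn - 1)) {
        dt <- b$times[tt + 1] - b$times[tt]
        u <- drop(z[tt, , drop = FALSE] %*% model$W)[seq_len(n)]
        for (i in seq_len(n)) {
          y0 <- b$y[tt, i]; y1 <- b$y[tt + 1, i]
          if (is.na(y0) || is.na(y1) || is.na(u[i])) next
          mu <- discrete_step(y0, u[i], model$alpha[i], model$beta[i], dt,
                              response, lo[i], hi[i])
          total <- total + student_t_marginal_density(y1, mu, noise$a, noise$b, log = TRUE)
        }
      }
    }
  }
  unname(total)
}
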