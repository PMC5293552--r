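#' Simulation configuration
#'
#' Settings for the synthetic benchmark generator. Topologies are directed
#' Erdos-Renyi graphs (independent edge probability
#' `mean_in_degree / (n_nodes - 1)`, no self loops); dynamics follow the
#' sigmoidal ODE of the inference model, integrated by fixed-substep Euler;
#' measurements get i.i.d. Gaussian noise. Every generator call is
#' deterministic given the seed.
#'
#' Replicate time series start from the unperturbed steady state plus a
#' random per-replicate displacement (`init_displacement_sd`, relative to
#' each molecule's steady level). This emulates the replicate-to-replicate
#' variability of multifactorial designs, where each repeat of an experiment
#' perturbs the starting state differently; without it a system observed at
#' equilibrium produces flat, uninformative series.
#'
#' @param n_nodes Number of molecules.
#' @param mean_in_degree Expected number of parents per molecule.
#' @param weight_range Magnitude range of nonzero weights.
#' @param sign_prob Probability that a weight is positive (activation).
#' @param alpha_range,beta_range Ranges of the decay (1/time) and production
#'   (concentration/time) parameters.
#' @param n_time_points Measurement time points per series.
#' @param dt Output time-interval length.
#' @param replicates Replicates per condition.
#' @param noise_sd Measurement-noise standard deviation; with
#'   `noise_type = "relative"` it is a fraction of each molecule's
#'   noise-free dynamic range.
#' @param noise_type `"relative"` or `"absolute"`.
#' @param pert_fraction Fraction of molecules that receive a dedicated
#'   perturbation node.
#' @param pert_strength Magnitude of the perturbation edge weight
#'   (inhibitory by default).
#' @param pert_timing `"constant"` (active over the whole series) or
#'   `"onoff"` (active on `[0, t_off)`).
#' @param t_off Offset time for `"onoff"` timing.
#' @param substeps Euler substeps per output interval; `substeps = 1`
#'   reproduces the inference-side discretization exactly.
#' @param init_displacement_sd Relative SD of the random initial-state
#'   displacement per replicate.
#' @param init_value Optional fixed initial value (scalar or length-n)
#'   overriding the default unperturbed-steady-state start.
#' @param seed Mandatory RNG seed.
#' @export
sim_config <- function(n_nodes = 10, mean_in_degree = 2,
                       weight_range = c(0.5, 2), sign_prob = 0.5,
                       alpha_range = c(0.2, 0.8), beta_range = c(0.5, 1.5),
                       n_time_points = 10, dt = 1, replicates = 3,
                       noise_sd = 0.05, noise_type = c("relative", "absolute"),
                       pert_fraction = 0.2, pert_strength = 2,
                       pert_timing = c("constant", "onoff"), t_off = Inf,
                       substeps = 10, init_displacement_sd = 0.3,
                       init_value = NULL, seed = NULL) {
  if (is.null(seed)) abort("A `seed` is mandatory for the simulator.")
  noise_type <- match.arg(noise_type)
  pert_timing <- match.arg(pert_timing)
  stopifnot(n_nodes >= 2, mean_in_degree >= 0, n_time_points >= 1,
            dt > 0, replicates >= 1, substeps >= 1,
            pert_fraction >= 0, pert_fraction <= 1)
  if (mean_in_degree >= n_nodes - 1) {
    abort("`mean_in_degree` must be below n_nodes - 1.")
  }
  as.list(environment())
}

#' Sample a random network topology
#'
#' Directed Erdos-Renyi graph with independent edge probability
#' `mean_in_degree / (n_nodes - 1)` and no self loops; weights drawn
#' uniformly in the magnitude range with random sign, decay and production
#' parameters from their ranges.
#'
#' @param config A [sim_config].
#' @return List with elements `model` ([network_model]) and `gold`
#'   (gold standard: tibble of true edges plus the perturbation target map).
#' @export
sample_topology <- function(config) {
  set.seed(config$seed)
  n <- config$n_nodes
  mols <- sprintf("G%d", seq_len(n))
  p_edge <- config$mean_in_degree / (n - 1)
  W <- matrix(0, n, n, dimnames = list(mols, mols))
  off <- which(row(W) != col(W))
  present <- runif(length(off)) < p_edge
  mag <- runif(sum(present), config$weight_range[1], config$weight_range[2])
  sgn <- ifelse(runif(sum(present)) < config$sign_prob, 1, -1)
  W[off[present]] <- mag * sgn
  model <- network_model(W,
                         alpha = runif(n, config$alpha_range[1], config$alpha_range[2]),
                         beta = runif(n, config$beta_range[1], config$beta_range[2]),
                         molecules = mols)
  gold <- gold_standard(W, molecules = mols)
  list(model = model, gold = gold)
}

#' Gold standard from a weight matrix
#'
#' @param W Weight matrix (source x target).
#' @param molecules Molecule names (gold edges are restricted to
#'   molecule-to-molecule pairs).
#' @param target_map Optional perturbation target map.
#' @export
gold_standard <- function(W, molecules = rownames(W), target_map = NULL) {
  sub <- W[molecules, molecules, drop = FALSE]
  idx <- which(sub != 0, arr.ind = TRUE)
  edges <- tibble::tibble(source = molecules[idx[, 1]],
                          target = molecules[idx[, 2]]) |>
    dplyr::arrange(.data$source, .data$target)
  structure(list(edges = edges, molecules = molecules,
                 target_map = target_map),
            class = "gold_standard")
}

#' Attach perturbation nodes to a sampled network
#'
#' Picks `ceiling(fraction * n)` distinct molecules uniformly and gives each
#' its own perturbation node connected by a single edge of weight
#' `-strength` (soft inhibitory intervention).
#'
#' @param model A [network_model] without perturbation nodes.
#' @param gold Matching gold standard.
#' @param fraction Fraction of molecules perturbed (`fraction * n >= 1`).
#' @param strength Magnitude of the perturbation edge weight.
#' @param seed RNG seed.
#' @return List with updated `model`, `gold` and the [pert_scheme].
#' @export
attach_perturbations <- function(model, gold, fraction, strength, seed) {
  n <- length(model$molecules)
  k <- ceiling(fraction * n)
  if (k < 1) abort("`fraction * n_nodes` must be at least 1.")
  set.seed(seed)
  targets <- sample(model$molecules, k)
  perts <- sprintf("P%d", seq_len(k))
  W <- matrix(0, n + k, n + k,
              dimnames = list(c(model$molecules, perts), c(model$molecules, perts)))
  W[model$molecules, model$molecules] <- model$W[model$molecules, model$molecules]
  W[cbind(perts, targets)] <- -strength
  model2 <- network_model(W, model$alpha, model$beta, model$molecules, perts)
  target_map <- stats::setNames(as.list(targets), perts)
  gold$target_map <- target_map
  list(model = model2, gold = gold,
       scheme = pert_scheme(target_map = target_map, type = "constant"))
}

# damped fixed-point iteration for the steady state of the dynamics;
# `x` holds perturbation-signal values, `clamp` forces molecules to a value
# (perfect knockout), `beta_scale` rescales production (knockdown etc.)
fixed_point_steady_state <- function(model, x = NULL, clamp = NULL,
                                     beta_scale = 1, tol = 1e-10,
                                     max_iter = 1e4, lambda = 0.5) {
  n <- length(model$molecules)
  m <- length(model$perturbations)
  if (is.null(x)) x <- rep(0, m)
  beta <- model$beta * rep_len(beta_scale, n)
  cidx <- match(names(clamp), model$molecules)
  y <- beta / (2 * model$alpha)
  if (!is.null(clamp)) y[cidx] <- unlist(clamp)
  S <- function(y) {
    u <- drop(c(y, x) %*% model$W)[seq_len(n)]
    s <- (beta / model$alpha) * sigmoid_response(u)
    if (!is.null(clamp)) s[cidx] <- unlist(clamp)
    s
  }
  for (it in seq_len(max_iter)) {
    s <- S(y)
    if (max(abs(s - y)) < tol) return(unname(s))
    y <- (1 - lambda) * y + lambda * s
  }
  abort(sprintf("Steady-state fixed point not reached in %d iterations.", max_iter))
}

# noise scale per molecule from noise-free values (list of matrices)
noise_scale <- function(traj_list, config) {
  if (config$noise_type == "absolute") {
    return(rep(config$noise_sd, ncol(traj_list[[1]])))
  }
  all <- do.call(rbind, traj_list)
  rng <- apply(all, 2, function(v) diff(range(v)))
  config$noise_sd * pmax(rng, 0.01)
}

#' Simulate perturbation time-series data
#'
#' Integrates the sigmoidal dynamics by fixed-substep Euler from the
#' unperturbed steady state (plus per-replicate random displacement) and
#' adds i.i.d. Gaussian measurement noise. With `m` perturbation nodes the
#' dataset has `m` conditions, condition `c` having only perturbation `c`
#' active; without perturbations there is a single observational condition.
#'
#' @param model A [network_model].
#' @param scheme A [pert_scheme] (may be `NULL` when the model has no
#'   perturbation nodes).
#' @param config A [sim_config].
#' @return List with `dataset` ([pert_dataset]), `gold` and the noise-free
#'   trajectories (`truth`).
#' @export
simulate_timeseries <- function(model, scheme = NULL, config) {
  set.seed(config$seed + 2L)
  n <- length(model$molecules)
  m <- length(model$perturbations)
  times <- (seq_len(config$n_time_points) - 1) * config$dt
  conditions <- if (m > 0) model$perturbations else "obs"
  t_off <- if (!is.null(scheme) && scheme$type == "onoff") scheme$offset else
    if (config$pert_timing == "onoff") config$t_off else Inf
  y_base <- if (!is.null(config$init_value)) rep_len(config$init_value, n) else
    fixed_point_steady_state(model, x = rep(0, m))

  h <- config$dt / config$substeps
  sig_at <- function(cond_j, t) {
    x <- rep(0, m)
    if (m > 0 && t < t_off) x[cond_j] <- 1
    x
  }
  blocks <- list(); truth <- list()
  for (cj in seq_along(conditions)) {
    for (r in seq_len(config$replicates)) {
      y0 <- y_base + if (config$init_displacement_sd > 0)
        rnorm(n, 0, config$init_displacement_sd * pmax(abs(y_base), 0.1)) else 0
      y0 <- pmax(y0, 0)
      Y <- matrix(NA_real_, length(times), n,
                  dimnames = list(NULL, model$molecules))
      Y[1, ] <- y0
      y <- y0
      for (tt in seq_len(length(times) - 1)) {
        for (s in seq_len(config$substeps)) {
          t_now <- times[tt] + (s - 1) * h
          x <- sig_at(cj, t_now)
          u <- drop(c(y, x) %*% model$W)[seq_len(n)]
          y <- y + h * (model$beta * sigmoid_response(u) - model$alpha * y)
        }
        if (any(!is.finite(y))) {
          abort("Trajectory blow-up: use a smaller dt (or ensure alpha * dt < 1).")
        }
        Y[tt + 1, ] <- y
      }
      X <- matrix(0, length(times), m, dimnames = list(NULL, model$perturbations))
      if (m > 0) for (tt in seq_along(times)) X[tt, ] <- sig_at(cj, times[tt])
      blocks[[length(blocks) + 1L]] <-
        list(condition = conditions[cj], replicate = r, times = times, y = Y, x = X)
      truth[[length(truth) + 1L]] <- Y
    }
  }
  sds <- noise_scale(truth, config)
  for (k in seq_along(blocks)) {
    noise <- matrix(rnorm(length(blocks[[k]]$y), 0, rep(sds, each = length(times))),
                    length(times), n)
    blocks[[k]]$y <- blocks[[k]]$y + noise
  }
  dataset <- structure(list(molecules = model$molecules,
                            perturbations = model$perturbations,
                            mode = "timeseries", blocks = blocks),
                       class = "pert_dataset")
  gold <- gold_standard(model$W, model$molecules,
                        target_map = if (!is.null(scheme)) scheme$target_map)
  list(dataset = dataset, gold = gold, truth = truth)
}

#' Simulate steady-state perturbation data
#'
#' One experiment per molecule: `"knockout"` clamps the target to 0,
#' `"knockdown"` halves its production, `"multifactorial"` rescales the
#' production of a random molecule subset by random factors. Steady states
#' are found by damped fixed-point iteration from the unperturbed steady
#' state; Gaussian noise is added to the single measurement row per
#' experiment. Knockout/knockdown datasets carry one perturbation node per
#' molecule (signal 1 in its own experiment); multifactorial targets are
#' unknown and no perturbation nodes are included.
#'
#' @param model A [network_model] (perturbation nodes, if any, are ignored
#'   here: interventions act directly on molecules).
#' @param config A [sim_config].
#' @param kind `"knockout"`, `"knockdown"` or `"multifactorial"`.
#' @return List with `dataset`, `gold`.
#' @export
simulate_steady_state <- function(model, config,
                                  kind = c("knockout", "knockdown", "multifactorial")) {
  kind <- match.arg(kind)
  set.seed(config$seed + 3L)
  n <- length(model$molecules)
  base <- network_model(model$W[model$molecules, model$molecules, drop = FALSE],
                        model$alpha, model$beta, model$molecules)
  rows <- list()
  for (i in seq_len(n)) {
    tgt <- model$molecules[i]
    y <- switch(kind,
      knockout = fixed_point_steady_state(base, clamp = stats::setNames(list(0), tgt)),
      knockdown = {
        bs <- rep(1, n); bs[i] <- 0.5
        fixed_point_steady_state(base, beta_scale = bs)
      },
      multifactorial = {
        sel <- runif(n) < 0.25
        if (!any(sel)) sel[sample.int(n, 1)] <- TRUE
        bs <- rep(1, n); bs[sel] <- runif(sum(sel), 0.25, 1.75)
        fixed_point_steady_state(base, beta_scale = bs)
      })
    rows[[i]] <- y
  }
  Y <- do.call(rbind, rows)
  colnames(Y) <- model$molecules
  sds <- noise_scale(list(Y), config)
  Yn <- Y + matrix(rnorm(length(Y), 0, rep(sds, each = n)), n, n)

  has_pert <- kind %in% c("knockout", "knockdown")
  pref <- if (kind == "knockout") "KO" else "KD"
  perts <- if (has_pert) sprintf("%s_%s", pref, model$molecules) else character(0)
  blocks <- lapply(seq_len(n), function(i) {
    x <- matrix(0, 1, length(perts), dimnames = list(NULL, perts))
    if (has_pert) x[1, i] <- 1
    list(condition = sprintf("exp%d", i), replicate = 1L, times = 0,
         y = Yn[i, , drop = FALSE], x = x)
  })
  dataset <- structure(list(molecules = model$molecules, perturbations = perts,
                            mode = "steadystate", blocks = blocks),
                       class = "pert_dataset")
  target_map <- if (has_pert) stats::setNames(as.list(model$molecules), perts)
  gold <- gold_standard(model$W, model$molecules, target_map = target_map)
  list(dataset = dataset, gold = gold, truth = Y)
}

#' One-call synthetic benchmark
#'
#' Samples a topology, optionally attaches perturbation nodes, and simulates
#' a time-series dataset with known ground truth.
#'
#' @param config A [sim_config].
#' @return List with `dataset`, `gold`, `scheme`, `model`.
#' @export
simulate_benchmark <- function(config) {
  topo <- sample_topology(config)
  scheme <- NULL
  model <- topo$model; gold <- topo$gold
  if (config$pert_fraction > 0 && ceiling(config$pert_fraction * config$n_nodes) >= 1) {
    at <- attach_perturbations(model, gold, config$pert_fraction,
                               config$pert_strength, seed = config$seed + 1L)
    model <- at$model; gold <- at$gold; scheme <- at$scheme
    if (config$pert_timing == "onoff") {
      scheme$type <- "onoff"; scheme$offset <- config$t_off
    }
  }
  sim <- simulate_timeseries(model, scheme, config)
  list(dataset = sim$dataset, gold = sim$gold, scheme = scheme, model = model)
}
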