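#' Build the per-node regression problem
#'
#' Rearranges the discretized dynamics into one linear regression per
#' molecule. In time-series mode each observed transition t -> t+1
#' contributes a row `y_i(t+1) = sum_p w~_p z_p(t) dt + d y_i(t) + c0 dt +
#' noise`, where `w~` are the effective (production-absorbed) weights,
#' `d = 1 - alpha dt` is the decay coefficient and `c0` a linearization
#' constant. In steady-state mode each experiment contributes one row with
#' no decay column and no time interval. Candidate parents are all other
#' molecules plus the perturbation nodes (restricted to mapped ones when the
#' perturbation scheme has known targets). Rows with a missing target or
#' missing regulators are excluded.
#'
#' @param dataset A (preprocessed) [pert_dataset].
#' @param node Molecule name or index.
#' @param bounds Optional [compute_clip_bounds] output; attaches per-row
#'   measurement bounds for the clipped response.
#' @param scheme Optional [pert_scheme]; a known `target_map` restricts
#'   which perturbation nodes are candidate parents.
#' @param include_intercept Include the linearization-constant column?
#' @return Object of class `node_problem`.
#' @export
build_node_problem <- function(dataset, node, bounds = NULL, scheme = NULL,
                               include_intercept = TRUE) {
  if (is.numeric(node)) node <- dataset$molecules[node]
  if (!node %in% dataset$molecules) abort(sprintf("Unknown molecule `%s`.", node))
  perts <- dataset$perturbations
  if (!is.null(scheme) && !is.null(scheme$target_map)) {
    perts <- names(scheme$target_map)[
      purrr::map_lgl(scheme$target_map, function(tg) node %in% tg)]
  }
  parents <- c(setdiff(dataset$molecules, node), perts)
  ts_mode <- dataset$mode == "timeseries"

  rows <- list(); targ <- list(); dts <- list(); los <- list(); his <- list()
  for (b in dataset$blocks) {
    z <- block_z(b)
    lo <- -Inf; hi <- Inf
    if (!is.null(bounds)) {
      bb <- bounds[bounds$condition == b$condition &
                     bounds$replicate == b$replicate &
                     bounds$molecule == node, ]
      if (nrow(bb)) { lo <- bb$lower[1]; hi <- bb$upper[1] }
    }
    if (ts_mode) {
      tn <- length(b$times)
      if (tn < 2) next
      dt <- diff(b$times)
      Zp <- z[-tn, parents, drop = FALSE] * dt
      self <- b$y[-tn, node]
      mat <- cbind(Zp, .self = self)
      if (include_intercept) mat <- cbind(mat, `(Intercept)` = dt)
      rows[[length(rows) + 1L]] <- mat
      targ[[length(targ) + 1L]] <- b$y[-1, node]
      dts[[length(dts) + 1L]] <- dt
    } else {
      mat <- z[1, parents, drop = FALSE]
      if (include_intercept) mat <- cbind(mat, `(Intercept)` = 1)
      rows[[length(rows) + 1L]] <- mat
      targ[[length(targ) + 1L]] <- b$y[1, node]
      dts[[length(dts) + 1L]] <- NA_real_
    }
    los[[length(los) + 1L]] <- rep(lo, nrow(rows[[length(rows)]]))
    his[[length(his) + 1L]] <- rep(hi, nrow(rows[[length(rows)]]))
  }
  X <- do.call(rbind, rows)
  y <- unlist(targ)
  dt <- unlist(dts)
  lo <- unlist(los); hi <- unlist(his)
  keep <- !is.na(y) & !apply(X, 1, anyNA)
  X <- X[keep, , drop = FALSE]; y <- y[keep]; dt <- dt[keep]
  lo <- lo[keep]; hi <- hi[keep]
  if (length(y) < 2) {
    abort(sprintf("Fewer than 2 usable transition rows for molecule `%s`.", node))
  }
  structure(list(node = node, X = X, y = y, dt = dt,
                 parents = parents, mode = dataset$mode,
                 has_self = ts_mode, has_intercept = include_intercept,
                 lower = lo, upper = hi),
            class = "node_problem")
}

#' @export
print.node_problem <- function(x, ...) {
  cat(sprintf("<node_problem: %s, %d rows, %d candidate parents, %s mode>\n",
              x$node, length(x$y), length(x$parents), x$mode))
  invisible(x)
}

# per-molecule measurement-noise variance by method of moments from
# differenced series (second differences where possible: for a smooth signal
# var(diff(y, d = 2)) ~= 6 sigma^2); steady-state data have no differences,
# so a fixed fraction of the cross-experiment variance is used instead
estimate_noise_var <- function(dataset) {
  n <- n_molecules(dataset)
  out <- numeric(n); names(out) <- dataset$molecules
  for (i in seq_len(n)) {
    ests <- c(); wts <- c()
    for (b in dataset$blocks) {
      v <- b$y[, i]; v <- v[!is.na(v)]
      if (dataset$mode == "timeseries" && length(v) >= 4) {
        ests <- c(ests, var(diff(v, differences = 2)) / 6)
        wts <- c(wts, length(v) - 2)
      } else if (dataset$mode == "timeseries" && length(v) >= 3) {
        ests <- c(ests, var(diff(v)) / 2); wts <- c(wts, length(v) - 1)
      }
    }
    if (dataset$mode == "steadystate" || !length(ests)) {
      allv <- unlist(purrr::map(dataset$blocks, function(b) b$y[, i]))
      out[i] <- 0.25 * var(allv, na.rm = TRUE)
    } else {
      out[i] <- sum(ests * wts) / sum(wts)
    }
    if (!is.finite(out[i]) || out[i] <= 0) out[i] <- 1e-4
    out[i] <- max(out[i], 1e-8)
  }
  out
}

#' Infer the posterior over one node's incoming edges
#'
#' Runs the spike-and-slab EP solver on a [build_node_problem] output:
#' candidate-parent columns get the spike-and-slab prior with per-edge
#' inclusion probabilities taken from `prior`, the decay column a
#' `N(1, 1)` prior (decay near zero leaves `d = 1 - alpha dt` near one) and
#' the intercept a broad Gaussian. Returns marginal weight means, variances
#' and inclusion probabilities, the EP evidence approximation, and (in
#' time-series mode) the decay estimate `alpha_hat = (1 - d_hat) / mean(dt)`.
#'
#' @param problem A `node_problem`.
#' @param prior A [spike_slab_prior].
#' @param noise_var Known/estimated Gaussian noise variance
#'   (`noise_mode = "gaussian"`).
#' @param noise A [noise_model] for `noise_mode = "student_t"`.
#' @param max_iters,tol,damping,order,seed EP controls, see [ep_spike_slab].
#' @param noise_mode `"gaussian"` (default) or `"student_t"`.
#' @param response `"linear"` or `"clipped"` (student_t mode).
#' @return Object of class `node_posterior`.
#' @export
ep_infer_node <- function(problem, prior, noise_var = NULL,
                          noise = noise_model(), max_iters = 20, tol = 1e-4,
                          damping = 0.8, order = "fixed", seed = NULL,
                          noise_mode = c("gaussian", "student_t"),
                          response = c("linear", "clipped")) {
  noise_mode <- match.arg(noise_mode)
  response <- match.arg(response)
  P <- ncol(problem$X)
  np <- length(problem$parents)
  rho <- rep(NA_real_, P)
  rho[seq_len(np)] <- prior$rho[cbind(problem$parents, rep(problem$node, np))]
  gidx <- which(is.na(rho))
  gm <- numeric(length(gidx)); gv <- rep(prior$slab_var, length(gidx))
  cn <- colnames(problem$X)
  gm[cn[gidx] == ".self"] <- 1
  gv[cn[gidx] == ".self"] <- 1
  fit <- ep_spike_slab(problem$X, problem$y, rho, noise_var = noise_var,
                       slab_var = prior$slab_var, spike_var = prior$spike_var,
                       gauss_mean = gm, gauss_var = gv,
                       max_iters = max_iters, tol = tol, damping = damping,
                       order = order, seed = seed, noise_mode = noise_mode,
                       noise = noise, response = response,
                       lower = problem$lower, upper = problem$upper)
  coef <- tibble::tibble(
    term = cn,
    role = dplyr::case_when(cn == ".self" ~ "decay",
                            cn == "(Intercept)" ~ "intercept",
                            TRUE ~ "parent"),
    mean = fit$mean, sd = fit$sd, inclusion = fit$inclusion,
    rho0 = rho)
  alpha_hat <- NA_real_
  if (problem$has_self && !fit$failed) {
    d_hat <- fit$mean[cn == ".self"]
    alpha_hat <- (1 - d_hat) / mean(problem$dt, na.rm = TRUE)
  }
  structure(list(node = problem$node, coefficients = coef,
                 alpha_hat = alpha_hat, log_evidence = fit$log_evidence,
                 iterations = fit$iterations, converged = fit$converged,
                 failed = fit$failed, n_skipped = fit$n_skipped,
                 n_rows = length(problem$y)),
            class = "node_posterior")
}

#' @export
print.node_posterior <- function(x, ...) {
  cat(sprintf("<node_posterior: %s%s, %d rows, %d iterations%s>\n",
              x$node, if (x$failed) " [FAILED]" else "", x$n_rows,
              x$iterations, if (x$converged) ", converged" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Infer the full network
#'
#' The main entry point: preprocesses the dataset as configured, solves the
#' per-node spike-and-slab regression independently for every molecule
#' (parallelizable across nodes with identical results), and assembles the
#' `(n+m) x (n+m)` matrix of posterior edge inclusion probabilities
#' (structural zeros for self edges and edges into perturbation nodes).
#' Per-node failures are flagged, not fatal: a failed node keeps its prior
#' inclusion probabilities.
#'
#' @param dataset A [pert_dataset].
#' @param prior Optional [spike_slab_prior]; defaults are built from the
#'   dataset and `scheme`.
#' @param config Named list of options overriding [default_config()].
#' @param scheme Optional [pert_scheme] (known perturbation targets).
#' @return Object of class `network_fit`.
#' @export
infer_network <- function(dataset, prior = NULL, config = list(), scheme = NULL) {
  cfg <- resolve_config(config)
  n <- n_molecules(dataset); m <- n_perturbations(dataset)
  nodes <- c(dataset$molecules, dataset$perturbations)

  noise_vars <- if (is.finite(cfg$noise.var)) {
    stats::setNames(rep(cfg$noise.var, n), dataset$molecules)
  } else estimate_noise_var(dataset)

  proc <- preprocess_dataset(dataset, variant = cfg$spline.variant,
                             n_points = if (cfg$spline.n_points > 0) cfg$spline.n_points,
                             log_scale = cfg$spline.log_scale,
                             center = cfg$center)
  bounds <- if (cfg$response == "clipped") compute_clip_bounds(proc) else NULL
  if (is.null(prior)) {
    prior <- spike_slab_prior(dataset$molecules, dataset$perturbations,
                              slab_var = cfg$prior.slab_var,
                              spike_var = cfg$prior.spike_var,
                              rho_mol = cfg$prior.rho_mol,
                              rho_pert = cfg$prior.rho_pert,
                              scheme = scheme, rho_known = cfg$prior.rho_known)
  }
  noise <- noise_model(cfg$noise.a, cfg$noise.b)

  run_node <- function(i) {
    node <- dataset$molecules[i]
    tryCatch({
      prob <- build_node_problem(proc, node, bounds = bounds, scheme = scheme,
                                 include_intercept = cfg$include_intercept)
      ep_infer_node(prob, prior, noise_var = noise_vars[i], noise = noise,
                    max_iters = cfg$ep.max_iters, tol = cfg$ep.tol,
                    damping = cfg$ep.damping, order = cfg$ep.order,
                    seed = cfg$seed + i, noise_mode = cfg$noise.mode,
                    response = cfg$response)
    }, error = function(e) {
      structure(list(node = node, coefficients = NULL, alpha_hat = NA_real_,
                     log_evidence = NA_real_, iterations = 0L,
                     converged = FALSE, failed = TRUE, n_skipped = 0L,
                     n_rows = 0L, error = conditionMessage(e)),
                class = "node_posterior")
    })
  }
  posts <- if (cfg$jobs > 1) {
    parallel::mclapply(seq_len(n), run_node, mc.cores = cfg$jobs,
                       mc.preschedule = TRUE)
  } else lapply(seq_len(n), run_node)

  scores <- matrix(0, n + m, n + m, dimnames = list(nodes, nodes))
  weights <- matrix(0, n + m, n + m, dimnames = list(nodes, nodes))
  weight_sd <- matrix(0, n + m, n + m, dimnames = list(nodes, nodes))
  alpha_hat <- stats::setNames(rep(NA_real_, n), dataset$molecules)
  for (i in seq_len(n)) {
    po <- posts[[i]]
    if (po$failed && is.null(po$coefficients)) {
      # prior-only fallback for nodes whose problem could not be built
      allowed <- setdiff(nodes, dataset$molecules[i])
      scores[allowed, i] <- prior$rho[allowed, i]
      next
    }
    par_rows <- po$coefficients[po$coefficients$role == "parent", ]
    scores[par_rows$term, i] <- par_rows$inclusion
    weights[par_rows$term, i] <- par_rows$mean
    weight_sd[par_rows$term, i] <- par_rows$sd
    alpha_hat[i] <- po$alpha_hat
  }
  if (dataset$mode != "timeseries") alpha_hat[] <- NA_real_

  node_info <- purrr::map_dfr(posts, function(po) tibble::tibble(
    node = po$node, n_rows = po$n_rows, iterations = po$iterations,
    converged = po$converged, failed = po$failed, n_skipped = po$n_skipped,
    log_evidence = po$log_evidence))
  node_info$noise_var <- noise_vars

  structure(list(scores = scores, weights = weights, weight_sd = weight_sd,
                 alpha_hat = alpha_hat, molecules = dataset$molecules,
                 perturbations = dataset$perturbations, mode = dataset$mode,
                 node_info = node_info, posteriors = posts, config = cfg),
            class = "network_fit")
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf("<network_fit: %d molecules, %d perturbation nodes (%s mode)>\n",
              length(x$molecules), length(x$perturbations), x$mode))
  cat(sprintf("  %d/%d nodes converged, %d failed\n",
              sum(x$node_info$converged), nrow(x$node_info),
              sum(x$node_info$failed)))
  invisible(x)
}

#' Tidy a network fit into an edge table
#'
#' One row per candidate edge (self edges and edges into perturbation nodes
#' are structurally excluded), sorted by decreasing posterior inclusion
#' probability.
#'
#' @param x A `network_fit`.
#' @param ... Unused.
#' @method tidy network_fit
#' @export
tidy.network_fit <- function(x, ...) {
  nodes <- c(x$molecules, x$perturbations)
  grid <- tidyr::expand_grid(source = nodes, target = x$molecules) |>
    dplyr::filter(.data$source != .data$target)
  grid |>
    dplyr::mutate(
      inclusion = x$scores[cbind(.data$source, .data$target)],
      weight = x$weights[cbind(.data$source, .data$target)],
      weight_sd = x$weight_sd[cbind(.data$source, .data$target)],
      edge_type = ifelse(.data$source %in% x$perturbations,
                         "perturbation", "molecule")) |>
    dplyr::arrange(dplyr::desc(.data$inclusion), .data$source, .data$target)
}

#' One-row summary of a network fit
#'
#' @param x A `network_fit`.
#' @param ... Unused.
#' @method glance network_fit
#' @export
glance.network_fit <- function(x, ...) {
  ed <- tidy(x)
  tibble::tibble(
    n_molecules = length(x$molecules),
    n_perturbations = length(x$perturbations),
    n_nodes_converged = sum(x$node_info$converged),
    n_nodes_failed = sum(x$node_info$failed),
    mean_iterations = mean(x$node_info$iterations),
    n_edges_half = sum(ed$inclusion > 0.5),
    total_log_evidence = sum(x$node_info$log_evidence, na.rm = TRUE))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
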