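#' Spike-and-slab edge prior
#'
#' Each candidate edge weight carries a two-component Gaussian mixture prior:
#' a broad slab `N(0, slab_var)` selected with probability `rho` (the prior
#' inclusion probability of the edge) and a narrow spike `N(0, spike_var)`
#' otherwise. `rho` is an `(n+m) x (n+m)` matrix indexed source x target.
#' Entries for forbidden edges -- self edges and edges into perturbation
#' nodes -- are 0 and immutable.
#'
#' Defaults: `rho = 0.1` for molecule-to-molecule edges; for
#' perturbation-to-molecule edges 0.5 when targets are unknown and 0.99 for
#' the known targets (capped below 1 to keep the spike component defined).
#'
#' @param molecules,perturbations Node name vectors.
#' @param slab_var Slab variance (default 10, large enough for low-bias
#'   weight estimates of present edges).
#' @param spike_var Spike variance (small positive; an exact delta would
#'   break the message-passing numerics).
#' @param rho_mol Default prior inclusion probability of molecule edges.
#' @param rho_pert Default for perturbation edges with unknown targets.
#' @param scheme Optional [pert_scheme]; if it has a known `target_map`, the
#'   mapped perturbation edges get `rho_known` and all other perturbation
#'   edges 0.
#' @param rho_known Prior inclusion probability of known perturbation
#'   targets.
#' @return Object of class `spike_slab_prior`.
#' @export
spike_slab_prior <- function(molecules, perturbations = character(0),
                             slab_var = 10, spike_var = 1e-4,
                             rho_mol = 0.1, rho_pert = 0.5,
                             scheme = NULL, rho_known = 0.99) {
  if (!(slab_var > spike_var && spike_var > 0)) {
    abort("Need slab_var > spike_var > 0.")
  }
  nodes <- c(molecules, perturbations)
  n <- length(molecules); m <- length(perturbations)
  rho <- matrix(0, n + m, n + m, dimnames = list(nodes, nodes))
  rho[seq_len(n), seq_len(n)] <- rho_mol
  diag(rho) <- 0
  if (m > 0) {
    if (!is.null(scheme) && !is.null(scheme$target_map)) {
      for (p in names(scheme$target_map)) {
        rho[p, scheme$target_map[[p]]] <- rho_known
      }
    } else {
      rho[n + seq_len(m), seq_len(n)] <- rho_pert
    }
  }
  structure(list(rho = rho, slab_var = slab_var, spike_var = spike_var,
                 molecules = molecules, perturbations = perturbations),
            class = "spike_slab_prior")
}

forbidden_edge <- function(prior, source, target) {
  m <- length(prior$perturbations)
  source == target | target %in% prior$perturbations
}

#' Inject prior knowledge about specific edges
#'
#' Overwrites the prior inclusion probability of listed edges, e.g. edges
#' known from the literature with 90% confidence. Entries addressing
#' forbidden edges (self edges, edges into perturbation nodes) are rejected
#' with a warning and leave the prior unchanged there.
#'
#' @param prior A [spike_slab_prior].
#' @param edges Tibble with columns `source`, `target`, `rho` (rho in (0, 1]).
#' @export
set_prior_edges <- function(prior, edges) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) return(prior)
  if (any(edges$rho <= 0 | edges$rho > 1)) {
    abort("Prior inclusion probabilities must lie in (0, 1].")
  }
  nodes <- rownames(prior$rho)
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(unknown)) {
    abort(sprintf("Unknown node(s) in prior edges: %s.", paste(unknown, collapse = ", ")))
  }
  bad <- forbidden_edge(prior, edges$source, edges$target)
  if (any(bad)) {
    warn(sprintf("Dropping %d prior entr%s for forbidden edges (self or into a perturbation node).",
                 sum(bad), if (sum(bad) == 1) "y" else "ies"))
    edges <- edges[!bad, ]
  }
  # a rho of exactly 1 would remove the spike; cap just below
  prior$rho[cbind(edges$source, edges$target)] <- pmin(edges$rho, 0.99)
  prior
}
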