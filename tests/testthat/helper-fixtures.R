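# Fixtures and independent oracles used across the suite.

# small hand-built time-series dataset (2 molecules, 1 perturbation,
# 1 condition, 1 replicate)
tiny_dataset <- function(values_a = c(0.2, 0.5, 0.9),
                         values_b = c(1.0, 0.8, 0.4),
                         times = c(0, 1, 2), signal = c(1, 1, 1)) {
  vals <- tidyr::expand_grid(time = times, molecule = c("A", "B")) |>
    dplyr::mutate(condition = "c1", replicate = 1L,
                  value = ifelse(molecule == "A",
                                 values_a[match(time, times)],
                                 values_b[match(time, times)]))
  sig <- tibble::tibble(condition = "c1", time = times,
                        perturbation = "P1", value = signal)
  pert_dataset(vals, sig, mode = "timeseries")
}

# quadrature oracle for the sigma^2-marginalized Gaussian density
quad_marginal_density <- function(y, mu, a, b) {
  stats::integrate(function(s2) {
    stats::dnorm(y, mu, sqrt(s2)) * b^a / gamma(a) * s2^(-a - 1) * exp(-b / s2)
  }, 0, Inf, rel.tol = 1e-10)$value
}

# brute-force pair-counting AUROC (ties count one half)
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ranking + gold over the full n-molecule universe from flat score/label
# vectors (pair order: expand.grid over ordered pairs, source != target)
universe_instance <- function(scores, labels) {
  np <- length(scores)
  n <- (1 + sqrt(1 + 4 * np)) / 2
  stopifnot(n == round(n))
  mols <- sprintf("M%d", seq_len(n))
  univ <- tidyr::expand_grid(source = mols, target = mols) |>
    dplyr::filter(source != target)
  ranking <- dplyr::mutate(univ, score = scores)
  gold <- structure(list(edges = univ[labels == 1, ], molecules = mols,
                         target_map = NULL),
                    class = "gold_standard")
  list(ranking = ranking, gold = gold)
}

# 1-D grid-integration oracle for the cavity x spike-and-slab hybrid
hybrid_moments_oracle <- function(m, v, rho, s1, s2) {
  w <- seq(m - 12 * sqrt(max(v, s1)), m + 12 * sqrt(max(v, s1)), length.out = 20001)
  f <- stats::dnorm(w, m, sqrt(v)) *
    (rho * stats::dnorm(w, 0, sqrt(s1)) + (1 - rho) * stats::dnorm(w, 0, sqrt(s2)))
  fs <- stats::dnorm(w, m, sqrt(v)) * rho * stats::dnorm(w, 0, sqrt(s1))
  h <- w[2] - w[1]
  z <- sum(f) * h
  mean <- sum(f * w) * h / z
  list(mean = mean, var = sum(f * w^2) * h / z - mean^2,
       inclusion = sum(fs) * h / z)
}
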