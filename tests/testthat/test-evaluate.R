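test_that("AUROC follows the rank/tie conventions on hand-checked cases", {
  inst <- universe_instance(c(0.9, 0.8, 0.2, 0.1, 0.05, 0.01),
                            c(1, 1, 0, 0, 0, 0))
  expect_equal(auroc(inst$ranking, inst$gold), 1)
  tie <- universe_instance(rep(0.5, 6), c(1, 1, 0, 0, 1, 0))
  expect_equal(auroc(tie$ranking, tie$gold), 0.5)
  # one concordant, one discordant pair
  half <- universe_instance(c(0.9, 0.8, 0.1, 0, 0, 0), c(1, 0, 1, 0, 0, 0))
  sub <- pair_count_auroc(c(0.9, 0.8, 0.1, 0, 0, 0), c(1, 0, 1, 0, 0, 0))
  expect_equal(auroc(half$ranking, half$gold), sub)
})

test_that("AUROC equals the pair-counting oracle on exhaustive small instances", {
  set.seed(1)
  for (n_mol in 2:4) {          # universes of 2, 6 and 12 ordered pairs
    np <- n_mol * (n_mol - 1)
    scores <- round(runif(np), 1)   # coarse grid forces ties
    for (rep in 1:3) {
      if (rep > 1) scores <- round(runif(np), 1)
      labs_all <- if (np <= 6) {
        as.matrix(expand.grid(rep(list(0:1), np)))
      } else {
        matrix(rbinom(50 * np, 1, 0.4), ncol = np)
      }
      for (k in seq_len(nrow(labs_all))) {
        labels <- labs_all[k, ]
        if (sum(labels) == 0 || sum(labels) == np) next
        inst <- universe_instance(scores, labels)
        expect_equal(auroc(inst$ranking, inst$gold),
                     pair_count_auroc(scores, labels))
      }
    }
  }
})

test_that("AUROC is invariant under monotone transforms and agrees with pROC", {
  set.seed(2)
  scores <- runif(12); labels <- rbinom(12, 1, 0.4)
  labels[1] <- 1; labels[2] <- 0
  inst <- universe_instance(scores, labels)
  a0 <- auroc(inst$ranking, inst$gold)
  for (f in list(function(x) 10 * x - 3, function(x) x^3, plogis)) {
    tr <- universe_instance(f(scores), labels)
    expect_equal(auroc(tr$ranking, tr$gold), a0, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a0, ref, tolerance = 1e-12)
})

test_that("AUPR follows the average-precision convention", {
  perfect <- universe_instance(c(0.9, 0.8, 0.2, 0.1, 0.05, 0.01),
                               c(1, 1, 0, 0, 0, 0))
  expect_equal(aupr(perfect$ranking, perfect$gold), 1)
  # single positive found at rank 2: precision 1/2 at full recall
  two <- universe_instance(c(0.9, 0.1, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0))
  expect_equal(aupr(two$ranking, two$gold), 0.5)
  # random scores concentrate around the prevalence (small positive
  # finite-sample bias of average precision aside)
  set.seed(3)
  np <- 90  # 10-molecule universe
  labels <- c(rep(1, 27), rep(0, 63))
  vals <- purrr::map_dbl(1:100, function(i) {
    inst <- universe_instance(runif(np), sample(labels))
    aupr(inst$ranking, inst$gold)
  })
  prev <- 27 / 90
  expect_lt(abs(mean(vals) - prev), 3 * stats::sd(vals) / 10 + 0.015)
})

test_that("curves are monotone, consistent with the areas, and antisymmetric", {
  inst <- universe_instance(c(0.9, 0.5, 0.3, 0.2, 0.15, 0.1),
                            c(1, 0, 1, 1, 0, 0))
  cv <- curves(inst$ranking, inst$gold)
  expect_true(all(diff(cv$roc$fpr) >= 0))
  expect_true(all(diff(cv$roc$tpr) >= 0))
  trap <- sum(diff(cv$roc$fpr) * (utils::head(cv$roc$tpr, -1) +
                                    utils::tail(cv$roc$tpr, -1)) / 2)
  expect_equal(trap, cv$auroc, tolerance = 1e-12)
  # one positive ranked first in a 2-edge universe
  first <- universe_instance(c(0.9, 0.1), c(1, 0))
  rf <- curves(first$ranking, first$gold)$roc
  expect_equal(rf$fpr, c(0, 0, 1))
  expect_equal(rf$tpr, c(0, 1, 1))
  # reversed perfect ranking and the complement identity
  rev <- universe_instance(c(0.1, 0.9), c(1, 0))
  expect_equal(auroc(rev$ranking, rev$gold), 0)
  set.seed(4)
  sc <- runif(12); lb <- rbinom(12, 1, 0.5); lb[1] <- 1; lb[2] <- 0
  a <- auroc(universe_instance(sc, lb)$ranking, universe_instance(sc, lb)$gold)
  b <- auroc(universe_instance(-sc, lb)$ranking, universe_instance(-sc, lb)$gold)
  expect_equal(a + b, 1, tolerance = 1e-12)
})

test_that("forbidden and degenerate inputs are rejected or excluded", {
  inst <- universe_instance(c(0.9, 0.8, 0.2, 0.1, 0.05, 0.01),
                            c(1, 1, 0, 0, 0, 0))
  # self edges in the submitted ranking are ignored, not evaluated
  with_self <- dplyr::bind_rows(inst$ranking,
                                tibble::tibble(source = "M1", target = "M1",
                                               score = 0.99))
  expect_equal(auroc(with_self, inst$gold), 1)
  dup <- dplyr::bind_rows(inst$ranking, inst$ranking[1, ])
  expect_error(auroc(dup, inst$gold), "at most once")
  bad <- inst$ranking; bad$score[1] <- Inf
  expect_error(auroc(bad, inst$gold), "finite")
  all_pos <- universe_instance(runif(6), rep(1, 6))
  expect_error(auroc(all_pos$ranking, all_pos$gold), "Degenerate")
  expect_error(aupr(universe_instance(runif(6), rep(0, 6))$ranking,
                    universe_instance(runif(6), rep(0, 6))$gold),
               "positive")
})

test_that("perturbation edges enter evaluation only on request", {
  cfg <- sim_config(n_nodes = 6, mean_in_degree = 1, pert_fraction = 0.5,
                    n_time_points = 8, replicates = 2, seed = 19)
  b <- simulate_benchmark(cfg)
  fit <- infer_network(b$dataset)
  r_all <- ranking_from_fit(fit, include_perturbation_edges = TRUE)
  expect_true(any(grepl("^P", r_all$source)))
  res_excl <- evaluate_ranking(ranking_from_fit(fit), b$gold)
  res_incl <- evaluate_ranking(r_all, b$gold, include_perturbation_edges = TRUE)
  expect_equal(res_excl$n_pos + res_excl$n_neg, 30)
  expect_equal(res_incl$n_pos, res_excl$n_pos + 3)
})
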