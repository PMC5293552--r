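test_that("topology sampling is deterministic and hits the expected density", {
  cfg <- sim_config(n_nodes = 10, mean_in_degree = 2, seed = 7)
  t1 <- sample_topology(cfg)
  t2 <- sample_topology(cfg)
  expect_identical(t1$model$W, t2$model$W)
  # binomial oracle: E[edges] = 90 * 2/9 = 20 over many seeds
  counts <- purrr::map_int(1:200, function(s) {
    nrow(sample_topology(sim_config(n_nodes = 10, mean_in_degree = 2,
                                    seed = s))$gold$edges)
  })
  se <- sqrt(90 * (2 / 9) * (7 / 9) / 200)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  empty <- sample_topology(sim_config(n_nodes = 10, mean_in_degree = 0, seed = 1))
  expect_equal(nrow(empty$gold$edges), 0)
})

test_that("perturbation attachment picks distinct single-target nodes", {
  cfg <- sim_config(n_nodes = 100, mean_in_degree = 2, seed = 2)
  topo <- sample_topology(cfg)
  at <- attach_perturbations(topo$model, topo$gold, 0.2, 2, seed = 3)
  expect_equal(length(at$model$perturbations), 20)
  expect_equal(lengths(at$scheme$target_map), rep(1L, 20),
               ignore_attr = TRUE)
  expect_equal(anyDuplicated(unlist(at$scheme$target_map)), 0)
  # perturbation columns of W stay structurally zero, rows carry one edge
  Wp <- at$model$W[at$model$perturbations, , drop = FALSE]
  expect_equal(rowSums(Wp != 0), rep(1, 20), ignore_attr = TRUE)
  expect_true(all(at$model$W[, at$model$perturbations] == 0))
  # different seeds give different target sets
  different <- purrr::map_lgl(1:5, function(s) {
    a <- attach_perturbations(topo$model, topo$gold, 0.2, 2, seed = s)
    b <- attach_perturbations(topo$model, topo$gold, 0.2, 2, seed = s + 50)
    !setequal(unlist(a$scheme$target_map), unlist(b$scheme$target_map))
  })
  expect_true(all(different))
  one <- attach_perturbations(topo$model, topo$gold, 0.01, 2, seed = 1)
  expect_equal(length(one$model$perturbations), 1)
})

test_that("isolated nodes relax monotonically to the analytic fixed point", {
  n <- 4
  mols <- sprintf("G%d", 1:n)
  model <- network_model(matrix(0, n, n), alpha = rep(1, n), beta = rep(1, n),
                         molecules = mols)
  cfg <- sim_config(n_nodes = n, mean_in_degree = 0, n_time_points = 21,
                    dt = 0.5, replicates = 1, noise_sd = 0,
                    noise_type = "absolute", pert_fraction = 0,
                    init_displacement_sd = 0, init_value = 0, seed = 1)
  sim <- simulate_timeseries(model, NULL, cfg)
  Y <- sim$dataset$blocks[[1]]$y
  expect_true(all(diff(Y[, 1]) > 0))
  expect_lt(max(abs(Y[21, ] - 0.5)), 1e-3)   # horizon 10 = 10 / alpha
})

test_that("an inhibitory perturbation lowers its target's steady level", {
  cfg <- sim_config(n_nodes = 6, mean_in_degree = 1, n_time_points = 30,
                    replicates = 1, noise_sd = 0, noise_type = "absolute",
                    pert_fraction = 0, init_displacement_sd = 0, seed = 13)
  topo <- sample_topology(cfg)
  at <- attach_perturbations(topo$model, topo$gold, 1 / 6, 3, seed = 2)
  target <- unlist(at$scheme$target_map)[1]
  unpert <- simulate_timeseries(topo$model, NULL, cfg)
  pert <- simulate_timeseries(at$model, at$scheme, cfg)
  y_u <- unpert$dataset$blocks[[1]]$y[30, target]
  y_p <- pert$dataset$blocks[[1]]$y[30, target]
  expect_lt(y_p, y_u)
})

test_that("simulation is bit-reproducible and bounded under the config grid", {
  for (nn in c(5, 12)) {
    for (pf in c(0, 0.25)) {
      cfg <- sim_config(n_nodes = nn, pert_fraction = pf, seed = 31)
      b1 <- simulate_benchmark(cfg)
      b2 <- simulate_benchmark(cfg)
      expect_identical(b1$dataset$blocks, b2$dataset$blocks)
      allv <- unlist(purrr::map(b1$dataset$blocks, function(b) b$y))
      expect_true(all(is.finite(allv)))
      # bounded by the saturation level beta / alpha plus noise headroom
      expect_lt(max(allv), max(1.5 / 0.2) + 1)
      expect_gt(min(allv), -1)
    }
  }
})

test_that("with one substep the simulator transitions equal the Euler map", {
  cfg <- sim_config(n_nodes = 5, mean_in_degree = 1.5, n_time_points = 8,
                    replicates = 2, substeps = 1, noise_sd = 0,
                    noise_type = "absolute", pert_fraction = 0.2, seed = 17)
  b <- simulate_benchmark(cfg)
  model <- b$model
  for (blk in b$dataset$blocks) {
    z <- cbind(blk$y, blk$x)
    for (tt in seq_len(nrow(blk$y) - 1)) {
      u <- drop(z[tt, ] %*% model$W)[seq_along(model$molecules)]
      mu <- discrete_step(blk$y[tt, ], u, model$alpha, model$beta,
                          dt = blk$times[tt + 1] - blk$times[tt])
      expect_equal(blk$y[tt + 1, ], mu, tolerance = 1e-12)
    }
  }
})

test_that("steady-state experiments honour their intervention semantics", {
  n <- 5
  mols <- sprintf("G%d", 1:n)
  model0 <- network_model(matrix(0, n, n), alpha = runif(n, 0.3, 0.8),
                          beta = runif(n, 0.5, 1.5), molecules = mols)
  cfg <- sim_config(n_nodes = n, seed = 23, noise_sd = 0, noise_type = "absolute")
  ss <- simulate_steady_state(model0, cfg, "knockout")
  # zero weights: everything sits at beta / (2 alpha), knocked-out node at 0
  for (i in seq_len(n)) {
    expect_equal(ss$truth[i, i], 0, ignore_attr = TRUE)
    others <- setdiff(seq_len(n), i)
    expect_equal(ss$truth[i, others],
                 (model0$beta / (2 * model0$alpha))[others],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # residual check on a connected network
  cfg2 <- sim_config(n_nodes = 6, mean_in_degree = 1.5, seed = 29,
                     noise_sd = 0, noise_type = "absolute")
  topo <- sample_topology(cfg2)
  kd <- simulate_steady_state(topo$model, cfg2, "knockdown")
  for (i in seq_len(6)) {
    bs <- rep(1, 6); bs[i] <- 0.5
    y <- kd$truth[i, ]
    u <- drop(y %*% topo$model$W)
    resid <- y - (bs * topo$model$beta / topo$model$alpha) * sigmoid_response(u)
    expect_lt(max(abs(resid)), 1e-8)
  }
  mf <- simulate_steady_state(topo$model, cfg2, "multifactorial")
  expect_equal(length(mf$dataset$perturbations), 0)
  expect_equal(length(mf$dataset$blocks), 6)
})

test_that("steady-state data support end-to-end inference", {
  cfg <- sim_config(n_nodes = 8, mean_in_degree = 1.5, seed = 41, noise_sd = 0.05)
  topo <- sample_topology(cfg)
  ko <- simulate_steady_state(topo$model, cfg, "knockout")
  fit <- infer_network(ko$dataset)
  res <- evaluate_ranking(ranking_from_fit(fit), ko$gold)
  expect_gt(res$auroc, 0.5)
})
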