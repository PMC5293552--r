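test_that("spike-and-slab site moments match 1-D numerical integration", {
  # single-component limits
  m1 <- spike_slab_site_moments(0.8, 0.5, rho = 1, slab_var = 10)
  expect_equal(m1$inclusion, 1)
  expect_equal(m1$mean, 0.8 * 10 / 10.5, tolerance = 1e-12)  # Gaussian product
  expect_equal(m1$var, 0.5 * 10 / 10.5, tolerance = 1e-12)
  m0 <- spike_slab_site_moments(0.8, 0.5, rho = 0, spike_var = 1e-4)
  expect_equal(m0$inclusion, 0)
  expect_lt(abs(m0$mean), 2e-4)
  # mixed case against the grid-integration oracle
  for (case in list(c(0, 1, 0.5), c(1.5, 0.3, 0.2), c(-2, 2, 0.9))) {
    got <- spike_slab_site_moments(case[1], case[2], case[3],
                                   slab_var = 10, spike_var = 1e-4)
    want <- hybrid_moments_oracle(case[1], case[2], case[3], 10, 1e-4)
    expect_equal(got$mean, want$mean, tolerance = 1e-6)
    expect_equal(got$var, want$var, tolerance = 1e-6)
    expect_equal(got$inclusion, want$inclusion, tolerance = 1e-6)
  }
  # a flat cavity near zero favours the spike (higher density at the origin)
  expect_lt(spike_slab_site_moments(0, 1, 0.5)$inclusion, 0.5)
  expect_error(spike_slab_site_moments(0, -1, 0.5), "cavity variance")
})

test_that("likelihood site updates behave in their limiting regimes", {
  # huge noise scale: the observation is uninformative, tilted ~= cavity
  up <- likelihood_site_update(0.3, cavity_mean = 1, cavity_var = 0.5,
                               noise = noise_model(1, 1e6))
  expect_equal(up$mean, 1, tolerance = 1e-3)
  expect_equal(up$var, 0.5, tolerance = 1e-3)
  # unbounded clipping equals linear mode
  lin <- likelihood_site_update(0.4, 0, 1, noise_model(2, 0.1), "linear")
  cl <- likelihood_site_update(0.4, 0, 1, noise_model(2, 0.1), "clipped",
                               lower = -Inf, upper = Inf)
  expect_equal(cl$mean, lin$mean, tolerance = 1e-12)
  expect_equal(cl$var, lin$var, tolerance = 1e-12)
  expect_error(likelihood_site_update(0, 0, -1, noise_model()), "cavity variance")
})

test_that("student-t EP approaches the conjugate solution in the Gaussian limit", {
  # a = large, b = a * sigma^2 concentrates the noise prior at sigma^2
  set.seed(21)
  z <- rnorm(40); sigma <- 0.1
  y <- 2 * z + rnorm(40, 0, sigma)
  fit <- ep_spike_slab(cbind(z), y, rho = 0.5, noise_mode = "student_t",
                       noise = noise_model(200, 200 * sigma^2), max_iters = 60)
  conj <- enumerate_spike_slab(cbind(z), y, sigma^2, 0.5)
  expect_false(fit$failed)
  expect_equal(fit$mean[1], conj$mean[1], tolerance = 0.05)
  expect_gt(fit$inclusion[1], 0.99)
})

test_that("EP with no sweeps returns the prior exactly", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  fit <- ep_spike_slab(X, y, rho = c(0.3, 0.7), noise_var = 1, max_iters = 0)
  expect_equal(fit$inclusion, c(0.3, 0.7))
  expect_equal(fit$mean, c(0, 0))
})

test_that("a strong single regressor is recovered with high confidence", {
  set.seed(5)
  z <- rnorm(50)
  y <- 2 * z + rnorm(50, 0, 0.02)
  fit <- ep_spike_slab(cbind(z), y, rho = 0.5, noise_var = 0.02^2,
                       max_iters = 50)
  en <- enumerate_spike_slab(cbind(z), y, 0.02^2, 0.5)
  expect_gt(fit$inclusion[1], 0.99)
  expect_lt(abs(fit$mean[1] - 2) / 2, 0.05)
  expect_equal(fit$inclusion[1], en$inclusion[1], tolerance = 0.05)
})

test_that("EP matches exhaustive enumeration across random instances", {
  set.seed(42)
  for (k in 1:20) {
    p <- sample(2:5, 1); n <- 30
    X <- matrix(rnorm(n * p), n, p)
    g <- runif(p) < 0.5
    w <- ifelse(g, rnorm(p, 0, sqrt(10)), 0)
    sig2 <- 0.25
    y <- drop(X %*% w) + rnorm(n, 0, sqrt(sig2))
    en <- enumerate_spike_slab(X, y, sig2, rho = 0.5)
    ep <- ep_spike_slab(X, y, rho = rep(0.5, p), noise_var = sig2,
                        max_iters = 100)
    expect_false(ep$failed)
    expect_true(all(abs(ep$inclusion - en$inclusion) <= 0.05))
    expect_true(all(abs(ep$mean - en$mean) <=
                      pmax(0.1 * abs(en$mean), 0.05)))
    # evidence approximation tracks the exact evidence
    expect_equal(ep$log_evidence, en$log_evidence, tolerance = 0.05)
  }
})

test_that("doubling the data never inflates posterior weight variances", {
  mean_var <- function(nrows, seed) {
    set.seed(seed)
    X <- matrix(rnorm(nrows * 3), nrows, 3)
    y <- drop(X %*% c(1.5, 0, -0.8)) + rnorm(nrows, 0, 0.5)
    fit <- ep_spike_slab(X, y, rho = rep(0.5, 3), noise_var = 0.25,
                         max_iters = 100)
    mean(fit$sd^2)
  }
  small <- purrr::map_dbl(1:10, function(s) mean_var(25, s))
  big <- purrr::map_dbl(1:10, function(s) mean_var(50, 100 + s))
  expect_lte(mean(big), mean(small) + 1e-9)
})

test_that("a zero prior inclusion probability enforces the spike", {
  set.seed(9)
  z <- rnorm(40)
  y <- 2 * z + rnorm(40, 0, 1)
  fit <- ep_spike_slab(cbind(z), y, rho = 0, noise_var = 1, max_iters = 50)
  expect_equal(fit$inclusion[1], 0)
  # the spike keeps the weight below noise scale: |w| <= 3 * sigma_spike
  expect_lte(abs(fit$mean[1]), 3 * sqrt(1e-4))
  # and it agrees with the closed-form ridge posterior under the spike
  ridge <- sum(z * y) / (sum(z^2) + 1 / 1e-4)
  expect_equal(fit$mean[1], ridge, tolerance = 1e-6)
})

test_that("node problems have the expected shape in each mode", {
  # 3 molecules, 1 perturbation, T = 5, 1 replicate
  times <- 0:4
  vals <- tidyr::expand_grid(time = times, molecule = c("G1", "G2", "G3")) |>
    dplyr::mutate(condition = "c1", replicate = 1L,
                  value = seq(0.1, by = 0.05, length.out = dplyr::n()))
  sig <- tibble::tibble(condition = "c1", time = times,
                        perturbation = "P1", value = 1)
  ds <- pert_dataset(vals, sig)
  prob <- build_node_problem(ds, "G1")
  expect_equal(length(prob$y), 4)
  expect_equal(prob$parents, c("G2", "G3", "P1"))
  expect_equal(colnames(prob$X), c("G2", "G3", "P1", ".self", "(Intercept)"))

  # known-target scheme: G3 is not a target of P1, so P1 drops out
  scheme <- pert_scheme(target_map = list(P1 = "G2"))
  p3 <- build_node_problem(ds, "G3", scheme = scheme)
  expect_false("P1" %in% p3$parents)
  p2 <- build_node_problem(ds, "G2", scheme = scheme)
  expect_true("P1" %in% p2$parents)

  # steady-state: one row per experiment, no decay column
  ssvals <- tidyr::expand_grid(condition = sprintf("e%d", 1:4),
                               molecule = c("G1", "G2", "G3")) |>
    dplyr::mutate(replicate = 1L, time = 0,
                  value = seq(0.1, by = 0.07, length.out = dplyr::n()))
  dss <- pert_dataset(ssvals, mode = "steadystate")
  ps <- build_node_problem(dss, "G1")
  expect_equal(length(ps$y), 4)
  expect_false(".self" %in% colnames(ps$X))
  expect_true(all(is.na(ps$dt)))

  expect_error(build_node_problem(ds, "nope"), "Unknown molecule")
})

test_that("node inference reports the prior when no sweeps run", {
  ds <- tiny_dataset()
  prior <- spike_slab_prior(ds$molecules, ds$perturbations)
  prob <- build_node_problem(ds, "A")
  post <- ep_infer_node(prob, prior, noise_var = 0.01, max_iters = 0)
  par <- post$coefficients[post$coefficients$role == "parent", ]
  expect_equal(par$inclusion, par$rho0)
})

test_that("all-zero data leaves inclusion probabilities at the prior", {
  vals <- tidyr::expand_grid(time = 0:4, molecule = c("G1", "G2", "G3")) |>
    dplyr::mutate(condition = "c1", replicate = 1L, value = 0)
  ds <- pert_dataset(vals)
  fit <- infer_network(ds, config = list(include_intercept = FALSE))
  ed <- tidy(fit)
  expect_true(all(ed$inclusion == 0.1))
})

test_that("parallel and serial node inference give identical score matrices", {
  cfg <- sim_config(n_nodes = 8, n_time_points = 8, replicates = 2, seed = 3)
  b <- simulate_benchmark(cfg)
  f1 <- infer_network(b$dataset, config = list(jobs = 1))
  f2 <- infer_network(b$dataset, config = list(jobs = 2))
  expect_identical(f1$scores, f2$scores)
})

test_that("knowing perturbation targets does not hurt recovery", {
  diffs <- purrr::map_dbl(1:5, function(s) {
    cfg <- sim_config(n_nodes = 10, n_time_points = 10, replicates = 3,
                      pert_fraction = 0.2, seed = s)
    b <- simulate_benchmark(cfg)
    f_unknown <- infer_network(b$dataset)
    f_known <- infer_network(b$dataset, scheme = b$scheme)
    auroc(ranking_from_fit(f_known), b$gold) -
      auroc(ranking_from_fit(f_unknown), b$gold)
  })
  expect_gte(mean(diffs), 0)
})

test_that("decay estimates recover the simulated decay rates on clean data", {
  cfg <- sim_config(n_nodes = 6, mean_in_degree = 1, n_time_points = 15,
                    replicates = 5, substeps = 1, noise_sd = 0.01,
                    pert_fraction = 0, seed = 8)
  b <- simulate_benchmark(cfg)
  fit <- infer_network(b$dataset)
  expect_gt(stats::cor(fit$alpha_hat, b$model$alpha), 0.8)
})
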