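test_that("the connectivity construction meets its structural contract", {
  p <- model_params(N = 300L, subset_size = 20L, n_subsets = 15L)
  w <- build_weight_matrix(p, seed = 40)
  W <- as.matrix(w$W)
  expect_equal(sum(w$is_inhibitory), 60L)           # 20% of columns
  expect_true(all(W[, w$is_inhibitory] <= 0))
  expect_true(all(W[, !w$is_inhibitory] >= 0))
  expect_true(all(diag(W) == 0))
  expect_true(all(w$indegree >= 1L & w$indegree <= 299L))
  expect_equal(unname(Matrix::rowSums(w$W != 0)), as.numeric(w$indegree))
  radius <- max(Mod(eigen(W, only.values = TRUE)$values))
  expect_equal(radius, 1, tolerance = 1e-6)
})

test_that("lognormal moment matching reproduces the stated variate moments", {
  set.seed(41)
  pr <- popcoupling:::.lnorm_param(0.5, 1)
  x <- rlnorm(2e5, pr["meanlog"], pr["sdlog"])
  expect_equal(mean(x), 0.5, tolerance = 0.02)
  expect_equal(var(x), 1, tolerance = 0.1)
})

test_that("zero input from an all-silent start stays silent", {
  p <- model_params(N = 200L, eta = 0, n_steps = 500L,
                    subset_size = 10L, n_subsets = 20L)
  w <- build_weight_matrix(p, seed = 42)
  sim <- simulate_network(w, p, seed = 43)
  expect_true(all(sim$counts == 0))
  expect_true(all(sim$rates == 0))
})

test_that("simulations are reproducible given a seed", {
  p <- model_params(N = 200L, n_steps = 2000L, eta = 2e-3,
                    subset_size = 10L, n_subsets = 20L)
  w <- build_weight_matrix(p, seed = 44)
  s1 <- simulate_network(w, p, seed = 45)
  s2 <- simulate_network(w, p, seed = 45)
  expect_identical(s1$counts, s2$counts)
})

test_that("without coupling or adaptation spike totals are binomial", {
  p <- model_params(N = 1000L, eta = 0.05, chi = 0, alpha = 0,
                    n_steps = 400L, model_bin = 50L)
  sim <- simulate_network(NULL, p, seed = 46)
  tot <- rowSums(sim$counts)
  # chi-squared goodness of fit against Binomial(400, 0.05)
  brk <- c(-Inf, 12, 15, 18, 21, 24, 27, Inf)
  obs <- table(cut(tot, brk))
  pr <- diff(pbinom(c(-Inf, 12, 15, 18, 21, 24, 27, Inf), 400, 0.05))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
  expect_equal(mean(tot), 400 * 0.05, tolerance = 0.05)
})

test_that("the adaptation fixed point matches the mean-field prediction", {
  p <- model_params(N = 1000L, eta = 8e-4, chi = 0, n_steps = 30000L)
  sim <- simulate_network(NULL, p, seed = 47)
  predicted <- p$eta / (1 + p$alpha * p$T_r * p$eta)
  expect_equal(mean(sim$rates), predicted, tolerance = 0.05)
})

test_that("a chi making the adaptation denominator non-positive is rejected", {
  expect_error(model_params(chi = -1), "chi")
})

test_that("perfectly synchronous counts give equal positive coupling", {
  v <- rep(c(3L, 0L, 2L, 0L, 1L), 8)
  f <- matrix(rep(v, each = 6), 6, byrow = FALSE)
  cp <- population_coupling(make_counts(f))$c_pop
  expect_true(all(abs(cp - cp[1]) < 1e-12))
  expect_gt(cp[1], 0)
})

test_that("the model partition is disjoint and covers the population", {
  p <- model_params(N = 200L, eta = 2e-3, n_steps = 2000L,
                    subset_size = 10L, n_subsets = 20L)
  w <- build_weight_matrix(p, seed = 48)
  sim <- simulate_network(w, p, seed = 49)
  mpc <- model_population_coupling(sim, p, seed = 50)
  all_idx <- sort(unname(unlist(mpc$groups)))
  expect_equal(all_idx, 1:200)
  expect_equal(lengths(mpc$groups), rep(10L, 20L), ignore_attr = TRUE)
})

test_that("uncoupled neurons have near-zero mean population coupling", {
  p <- model_params(N = 400L, eta = 5e-3, chi = 0, alpha = 0,
                    n_steps = 10000L, subset_size = 20L, n_subsets = 20L)
  sim <- simulate_network(NULL, p, seed = 51)
  mpc <- model_population_coupling(sim, p, seed = 52)
  expect_lt(abs(mean(mpc$c_pop, na.rm = TRUE)), 0.05)
})

test_that("sweeps average over seeds into one row per grid point", {
  p <- model_params(N = 200L, n_steps = 1000L, eta = 2e-3,
                    subset_size = 10L, n_subsets = 20L)
  tab <- sweep_model(data.frame(eta = 2e-3, chi = 0), p, seeds = 1:2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_seeds, 2L)
  expect_equal(nrow(model_preset_grid("fig3c")), 5L)
  expect_equal(nrow(model_preset_grid("fig3d")), 5L)
  expect_equal(nrow(model_preset_grid("fig3e")), 3L)
})
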