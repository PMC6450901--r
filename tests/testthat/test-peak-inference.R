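test_that("peakiness is 1 on a noiseless peak and 0 on monotone data", {
  x <- seq(0, 1, length.out = 60)
  y <- -(x - 0.5)^2
  pk <- peakiness(x, y)
  expect_equal(pk$P, 1)
  expect_lt(abs(pk$x_star - 0.5), 0.05)
  expect_equal(pk$rho_left, 1)
  expect_equal(pk$rho_right, -1)

  mono <- peakiness(x, 2 * x + 1)
  expect_equal(mono$P, 0)
  expect_true(is.na(mono$x_star))

  expect_error(peakiness(x[1:20], y[1:20]), "points")
})

test_that("peakiness is invariant to strictly monotone transforms of x and y", {
  set.seed(30)
  x <- runif(80)
  y <- -(x - 0.4)^2 + rnorm(80, 0, 0.02)
  p0 <- peakiness(x, y)$P
  expect_equal(peakiness(x, exp(3 * y))$P, p0, tolerance = 1e-12)
  expect_equal(peakiness(x^3, y)$P, p0, tolerance = 1e-12)
  expect_gt(p0, 0.5)
})

test_that("the permutation test is deterministic given a seed and maximally
           significant for a noiseless peak", {
  x <- seq(0, 1, length.out = 60)
  y <- -(x - 0.5)^2
  t1 <- peak_permutation_test(x, y, n_shuffles = 200, seed = 5)
  t2 <- peak_permutation_test(x, y, n_shuffles = 200, seed = 5)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$shuffle_P, t2$shuffle_P)
  expect_equal(t1$p_value, 1 / 201)  # P_obs = 1 dominates every shuffle
})

test_that("a planted noisy peak is localized in the central third of x", {
  set.seed(31)
  hits <- 0
  for (r in 1:100) {
    x <- runif(100)
    amp <- 0.5
    y <- amp * exp(-(x - 0.5)^2 / 0.02) + rnorm(100, 0, amp)
    xs <- peakiness(x, y)$x_star
    rng <- range(x)
    third <- rng[1] + diff(rng) * c(1, 2) / 3
    if (!is.na(xs) && xs >= third[1] && xs <= third[2]) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("session consistency criteria follow the quadratic fit shape", {
  xs <- seq(0.1, 0.9, length.out = 12)
  down <- session_consistency(xs, -(xs - 0.5)^2, pooled_x_star = 0.5,
                              pooled_x_range = 1)
  expect_true(down$consistent)
  expect_equal(down$criterion, "curvature+location")
  expect_lt(abs(down$fit_max_x - 0.5), 1e-8)

  left <- session_consistency(seq(0.05, 0.3, length.out = 10),
                              seq(1, 2, length.out = 10),
                              pooled_x_star = 0.6, pooled_x_range = 1)
  expect_true(left$consistent)
  expect_equal(left$criterion, "slope-left")

  right <- session_consistency(seq(0.7, 0.95, length.out = 10),
                               seq(2, 1, length.out = 10),
                               pooled_x_star = 0.6, pooled_x_range = 1)
  expect_true(right$consistent)
  expect_equal(right$criterion, "slope-right")

  up <- session_consistency(xs, (xs - 0.5)^2, pooled_x_star = 0.5,
                            pooled_x_range = 1)
  expect_false(up$consistent)

  skipped <- session_consistency(c(0.1, 0.2, 0.3), c(1, 2, 3), 0.5, 1)
  expect_equal(skipped$criterion, "skipped")
  expect_true(is.na(skipped$consistent))
})

test_that("the consistency count is significant for shared-peak sessions", {
  set.seed(32)
  mk <- function() {
    x <- runif(30)
    list(x = x, y = exp(-(x - 0.5)^2 / 0.02) + rnorm(30, 0, 0.15))
  }
  sessions <- replicate(8, mk(), simplify = FALSE)
  res <- consistency_count_test(sessions, n_randomizations = 200, seed = 33)
  expect_lt(res$p_value, 0.05)
  expect_gte(res$count, res$n_sessions / 2)

  expect_error(consistency_count_test(list(list(x = 1:3, y = 1:3)),
                                      n_randomizations = 10),
               "at least 2 sessions")
})

test_that("median normalization rescales each session to unit medians", {
  s1 <- list(session_id = "a", x = c(1, 2, 3, 4, 6), y = c(2, 4, 6, 8, 10))
  s2 <- list(session_id = "b", x = c(10, 20, 30, 40, 60), y = c(1, 2, 3, 4, 5))
  out <- median_normalize(list(s1, s2))
  expect_equal(out$table$x[1:5], c(1, 2, 3, 4, 6) / 3)
  for (id in c("a", "b")) {
    expect_equal(median(out$table$x[out$table$session == id]), 1)
    expect_equal(median(out$table$y[out$table$session == id]), 1)
  }
  s3 <- list(session_id = "c", x = c(-1, 0, 1, 0, 0), y = 1:5)
  out2 <- median_normalize(list(s1, s3))
  expect_match(out2$log, "session c", all = FALSE)
  expect_false("c" %in% out2$table$session)
})

test_that("moving quartile summaries behave on flat and peaked data", {
  x <- seq(0, 1, length.out = 40)
  flat <- moving_quartile_summary(x, rep(2, 40), window = 10)
  expect_true(all(flat$y_median == 2 & flat$y_q1 == 2 & flat$y_q3 == 2))

  single <- moving_quartile_summary(x, x, window = 40)
  expect_equal(nrow(single), 1L)

  y <- -(x - 0.5)^2
  cur <- moving_quartile_summary(x, y, window = 8)
  expect_lt(abs(cur$x_center[which.max(cur$y_median)] - 0.5), 8 / 40)
})
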