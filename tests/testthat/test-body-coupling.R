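test_that("event detection applies the mean-crossing rule", {
  ev <- detect_events(c(0, 0, 4, 4, 0, 0), sample_rate_hz = 1)
  expect_equal(ev$onsets, 2)
  expect_equal(ev$cessations, 4)

  expect_length(detect_events(rep(3, 100), sample_rate_hz = 1)$onsets, 0L)

  ramp <- seq(0, 10, length.out = 300)  # 30 s at 10 Hz, crosses mean once
  ev2 <- detect_events(ramp, sample_rate_hz = 10)
  expect_length(ev2$onsets, 1L)
  expect_length(ev2$cessations, 0L)
})

test_that("event detection debounces chatter and keeps alternation", {
  set.seed(8)
  n <- 6000
  base <- rep(c(0, 10), each = 500)[c(rep(1:1000, 6))]
  speed <- pmax(0, base + rnorm(n, 0, 3))
  ev <- detect_events(speed, sample_rate_hz = 100)
  expect_gt(length(ev$onsets), 0L)
  merged <- rbind(data.frame(t = ev$onsets, on = TRUE),
                  data.frame(t = ev$cessations, on = FALSE))
  merged <- merged[order(merged$t), ]
  expect_true(all(diff(merged$on) != 0))  # strict alternation
  expect_true(all(diff(ev$onsets) >= 0.5 - 1e-9))
  expect_true(all(diff(ev$cessations) >= 0.5 - 1e-9))
})

test_that("surrogate slices match a brute-force circular recomputation", {
  set.seed(10)
  dur <- 200; fs <- 100
  n <- dur * fs
  speed <- abs(sin(2 * pi * 0.5 * (0:(n - 1)) / fs)) * 20 + 5
  spk <- sort(runif(300, 0, dur))
  cnt <- popcoupling:::.counts_per_sample(spk, fs, n)
  cc <- popcoupling:::.circular_crosscorr(cnt, speed)
  for (o in c(3500L, 12000L, n - 3100L)) {
    sl <- popcoupling:::.sta_slices(cc, sum(cnt), o, sign = +1L)[, 1]
    idx <- popcoupling:::.sample_index(spk, fs, n)
    brute <- sta_brute(speed, ((idx - 1L + o) %% n) + 1L)
    expect_equal(sl, brute, tolerance = 1e-10)
  }
})

test_that("circular-shift surrogates preserve count and autocorrelation", {
  set.seed(12)
  spk <- sort(runif(200, 0, 120))
  surr <- shift_surrogate(spk, 120, 20)
  expect_true(all(lengths(surr) == length(spk)))
  expect_true(all(sapply(surr, function(s) all(s >= 0 & s < 120))))
  # a circular shift leaves the circular ISI multiset untouched
  cisi <- function(t) sort(diff(c(t, t[1] + 120)))
  expect_equal(cisi(surr[[1]]), cisi(spk), tolerance = 1e-9)
})

test_that("STABS is zero for constant speed and scale-invariant", {
  spk <- sort(runif(400, 0, 150))
  const <- rep(7, 15000)
  s <- stabs(spk, const)
  expect_equal(s$bc_s, 0, tolerance = 1e-10)

  set.seed(13)
  speed <- abs(sin(2 * pi * 0.5 * (0:14999) / 100)) * 30 + 2
  s1 <- stabs(spk, speed)
  s3 <- stabs(spk, 3 * speed)
  expect_equal(s1$bc_s, s3$bc_s, tolerance = 1e-8)
})

test_that("speed-locked spikes give a lag-0 STABS peak, random spikes do not", {
  dur <- 300; fs <- 100
  tt <- (0:(dur * fs - 1)) / fs
  speed <- (sin(2 * pi * 0.5 * tt) + 1) * 25  # 2 s period, peaks at 0.5+2k
  locked <- seq(0.5, dur - 2, by = 2)
  s <- stabs(locked, speed)
  expect_gt(s$bc_s, 0.2)
  expect_equal(s$waveform$lags_s[which.max(s$waveform$values)], 0,
               tolerance = 0.06)
  set.seed(14)
  s0 <- body_coupling_stabs(sort(runif(600, 0, dur)), speed,
                            n_surrogates = 200)
  expect_lt(s0$bc_s, s$bc_s / 5)
})

test_that("MTASR is flat for movement-independent units and bumps for locked ones", {
  set.seed(15)
  dur <- 600; fs <- 100; n <- dur * fs
  bout <- rep(rep(c(0, 1), each = 400), length.out = n)  # 4 s rest / 4 s move
  speed <- popcoupling::lowpass_zero_phase(bout * 40, 1, fs) + 1
  ev <- detect_events(speed, fs)
  expect_gte(length(ev$onsets), 5L)

  hom <- sort(runif(3 * dur, 0, dur))
  m0 <- mtasr(hom, ev, n)
  expect_lt(abs(mean(m0$onset$values) - 1), 0.05)

  after <- unlist(lapply(ev$onsets, function(t) t + runif(12, 0, 0.5)))
  after <- sort(after[after < dur - 1.2])
  m1 <- mtasr(after, ev, n)
  expect_gt(m1$bc_m, 3 * m0$bc_m)
})

test_that("BC_M and BC_S are invariant to uniform rate rescaling", {
  set.seed(16)
  dur <- 300; fs <- 100; n <- dur * fs
  bout <- rep(rep(c(0, 1), each = 300), length.out = n)
  speed <- popcoupling::lowpass_zero_phase(bout * 40, 1, fs) + 1
  ev <- detect_events(speed, fs)
  spk <- sort(runif(900, 0, dur))
  doubled <- sort(c(spk, spk))  # exactly twice the spike count per bin
  expect_equal(mtasr(doubled, ev, n)$bc_m, mtasr(spk, ev, n)$bc_m,
               tolerance = 1e-10)
  expect_equal(stabs(doubled, speed)$bc_s, stabs(spk, speed)$bc_s,
               tolerance = 1e-10)
})

test_that("significance requires strictly exceeding 95% of surrogates", {
  expect_true(significance(1, seq(0, 0.9, length.out = 1000)))
  surr <- seq(0.001, 1, length.out = 1000)
  expect_false(significance(median(surr), surr))
  # tie at the 95% rank does not count
  expect_false(significance(0.95, c(rep(0.1, 949), rep(0.95, 51))))
  expect_true(is.na(significance(NA_real_, surr)))
})

test_that("insufficient triggers or spikes yield flagged NA couplings", {
  ev <- structure(list(onsets = c(100, 200), cessations = c(150, 250),
                       threshold = 1, log = character(0)), class = "event_set")
  m <- mtasr(sort(runif(500, 0, 300)), ev, 30000)
  expect_true(is.na(m$bc_m))
  expect_equal(m$flag, "insufficient_events")
  s <- stabs(c(10, 20, 30), rep(1, 30000))
  expect_true(is.na(s$bc_s))
  expect_equal(s$flag, "insufficient_spikes")
})

test_that("BC_D finds the planted aspect and is monotone under duplication", {
  set.seed(17)
  fs <- 100; n <- 60000
  kin <- list(sample_rate_hz = fs,
              aspects = t(sapply(1:27, function(a) {
                popcoupling::lowpass_zero_phase(rnorm(n), 2, fs)
              })))
  lam <- pmax(0, kin$aspects[2, ]) * 30
  spk <- popcoupling:::.thin_poisson(lam, fs, n / fs)
  set.seed(18)
  d <- bcd(spk, kin, n_surrogates = 60)
  expect_equal(d$best_aspect_index, 2L)
  expect_gt(d$bc_d, 2 * sort(d$scores, decreasing = TRUE)[2])

  kin2 <- kin
  kin2$aspects[27, ] <- kin$aspects[2, ]
  set.seed(18)
  d2 <- bcd(spk, kin2, n_surrogates = 60)
  expect_gte(d2$bc_d + 1e-9, d$bc_d)
})

test_that("on rigid synthetic sessions BC_D flags the turning-equivalent family", {
  p <- synth_params(n_units = 2, duration_s = 600, a = c(0, 0), b = c(0, 0),
                    seed = 19)
  g <- generate_session(p)
  k <- compute_aspects(g$session$beads)
  set.seed(20)
  lam <- pmax(0, k$aspects[2, ]) * 8
  spk <- popcoupling:::.thin_poisson(lam, 100, 600)
  d <- bcd(spk, k, n_surrogates = 60)
  # under rigid turning, lateral bead velocities are degenerate with the
  # turning angular speed; any member of that family is a correct argmax
  turning_family <- c(2L, 3L + 3L * (0:7) + 2L)
  expect_true(d$best_aspect_index %in% turning_family)
  expect_gt(min(d$scores[turning_family]), 2 * max(d$scores[-turning_family]))
})

test_that("half-session body couplings agree on stationary synthetic sessions", {
  # a body-coupling population spanning the gain range, latent drive off:
  # both drives feed population covariance, so stability of the body-coupling
  # measures is probed on the sessions that isolate the movement drive
  p <- synth_params(n_units = 40, duration_s = 1800, seed = 21,
                    a = rep(0, 40), b = seq(0, 1, length.out = 40))
  g <- generate_session(p)
  k <- compute_aspects(g$session$beads)
  speed <- k$mean_body_speed
  n <- length(speed)
  half <- n %/% 2
  sp1 <- speed[1:half]; sp2 <- speed[(half + 1):n]
  ev1 <- detect_events(sp1); ev2 <- detect_events(sp2)
  bc1 <- bc2 <- m1 <- m2 <- numeric(40)
  for (i in 1:40) {
    tm <- g$session$spikes$spike_times[[i]]
    t1 <- tm[tm < half / 100]
    t2 <- tm[tm >= half / 100] - half / 100
    bc1[i] <- stabs(t1, sp1)$bc_s
    bc2[i] <- stabs(t2, sp2)$bc_s
    m1[i] <- mtasr(t1, ev1, half)$bc_m
    m2[i] <- mtasr(t2, ev2, half)$bc_m
  }
  ok <- is.finite(bc1) & is.finite(bc2)
  expect_gte(cor(bc1[ok], bc2[ok]), 0.6)
  ok2 <- is.finite(m1) & is.finite(m2)
  expect_gte(cor(m1[ok2], m2[ok2]), 0.6)
})
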