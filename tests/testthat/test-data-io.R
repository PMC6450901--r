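test_that("spike files parse, sort and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,spike_time_s", "u1,0.5", "u1,0.2", "u2,0.3"), f)
  sts <- read_spikes(f, duration_s = 1)
  expect_equal(sts$spike_times$u1, c(0.2, 0.5))
  expect_equal(sts$spike_times$u2, 0.3)
  expect_equal(length(sts$unit_ids), 2L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spikes(sts, f2)
  back <- read_spikes(f2, duration_s = 1)
  expect_identical(back$spike_times, sts$spike_times)
})

test_that("invalid spike files are rejected with the offending line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,spike_time_s", "u1,0.1", "u1,-1.0"), f)
  expect_error(read_spikes(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("unit_id,spike_time_s", f2)
  expect_error(read_spikes(f2), "empty")
})

test_that("bead files read on the 100 Hz grid, interpolating short gaps only", {
  n <- 120
  tms <- (seq_len(n) - 1) / 100
  full <- do.call(rbind, lapply(seq_along(BEAD_LABELS), function(b) {
    data.frame(time_s = tms, bead_label = BEAD_LABELS[b],
               x_mm = b * 10 + tms, y_mm = 0, z_mm = 30)
  }))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(full, f, row.names = FALSE, quote = FALSE)
  bt <- read_beads(f)
  expect_equal(dim(bt$positions), c(8L, n, 3L))
  expect_equal(bt$positions[3, , 1], 30 + tms)

  # one missing sample (10 ms gap) -> interpolated midpoint
  drop1 <- full[!(full$bead_label == "head" & abs(full$time_s - 0.5) < 1e-9), ]
  write.csv(drop1, f, row.names = FALSE, quote = FALSE)
  bt1 <- read_beads(f)
  expect_equal(bt1$positions[1, 51, 1], 10 + mean(c(0.49, 0.51)))

  # 200 ms gap -> error
  gap <- full[!(full$bead_label == "head" & full$time_s > 0.4 &
                  full$time_s < 0.6 + 1e-9), ]
  write.csv(gap, f, row.names = FALSE, quote = FALSE)
  expect_error(read_beads(f), "gap too long")

  # missing bead entirely
  nohead <- full[full$bead_label != "head", ]
  write.csv(nohead, f, row.names = FALSE, quote = FALSE)
  expect_error(read_beads(f), "missing bead")
})

test_that("exclusion rules drop slow units first, then short-handed sessions", {
  mk <- function(rates, dur = 1800) {
    spikes <- lapply(rates, function(r) {
      if (r == 0) numeric(0) else regular_spikes(r, dur)
    })
    names(spikes) <- sprintf("u%d", seq_along(rates))
    session("s1", spike_train_set(spikes, dur))
  }
  r1 <- apply_exclusions(mk(c(0.1, 0.6, 0.7, 0.8, 0.9, 1.0)))
  expect_false(r1$excluded)
  expect_equal(length(r1$session$spikes$unit_ids), 5L)
  expect_match(r1$log, "u1", all = FALSE)

  r2 <- apply_exclusions(mk(rep(0.4, 5)))
  expect_true(r2$excluded)
  expect_equal(length(r2$session$spikes$unit_ids), 0L)

  r3 <- apply_exclusions(mk(rep(2, 4)))
  expect_true(r3$excluded)
  expect_equal(length(r3$session$spikes$unit_ids), 4L)
})

test_that("apply_exclusions is idempotent", {
  spikes <- lapply(c(0.2, 1, 1.5, 2, 2, 3), function(r) regular_spikes(r, 600))
  names(spikes) <- sprintf("u%d", 1:6)
  s <- session("s", spike_train_set(spikes, 600))
  once <- apply_exclusions(s)
  twice <- apply_exclusions(once$session)
  expect_identical(twice$session$spikes, once$session$spikes)
  expect_identical(twice$excluded, once$excluded)
  expect_length(twice$log, 0L)
})

test_that("coupling tables round-trip through CSV", {
  tab <- data.frame(session_id = "s1", unit_id = c("a", "b"),
                    rate_hz = c(1.25, 2.5), c_pop = c(0.5, -1.5),
                    bc_m = c(0.125, 0.25), bc_s = c(0.1, 0.2),
                    bc_d = c(1.5, 2.25),
                    bc_m_significant = c(TRUE, FALSE),
                    bc_s_significant = c(FALSE, TRUE),
                    best_aspect_index = c(2L, 14L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_coupling_table(tab, f)
  expect_identical(read_coupling_table(f), tab)
})

test_that("session construction enforces duration agreement with beads", {
  spikes <- spike_train_set(list(u1 = c(0.5, 1)), duration_s = 2)
  pos <- array(rnorm(8 * 200 * 3), c(8, 200, 3))
  expect_s3_class(session("ok", spikes, bead_trajectories(pos)), "session")
  pos_bad <- array(rnorm(8 * 150 * 3), c(8, 150, 3))
  expect_error(session("bad", spikes, bead_trajectories(pos_bad)), "disagree")
})
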