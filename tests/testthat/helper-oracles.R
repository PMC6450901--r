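# independent oracles and small fixture builders used across the test files

# wrap a plain count matrix as a binned_counts object
make_counts <- function(mat, bin_width_s = 0.25) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("u", seq_len(nrow(mat)))
  structure(list(counts = mat, bin_width_s = bin_width_s,
                 n_bins = ncol(mat), unit_ids = rownames(mat)),
            class = "binned_counts")
}

# naive double-loop population coupling, straight from the definition
cpop_naive <- function(f) {
  n <- nrow(f); T <- ncol(f)
  mu <- sapply(seq_len(n), function(j) mean(f[j, ]))
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_len(T)) {
      P <- 0
      for (j in seq_len(n)) if (j != i) P <- P + (f[j, t] - mu[j])
      acc <- acc + f[i, t] * P
    }
    out[i] <- acc / sum(f[i, ])
  }
  out
}

# brute-force circular spike-triggered average at given sample indices
sta_brute <- function(series, trig_idx, n_lag = 100L) {
  n <- length(series)
  sapply(-n_lag:n_lag, function(l) {
    mean(series[((trig_idx - 1L + l) %% n) + 1L])
  })
}

# rigid-body bead positions: offsets rotated by heading theta, translated by com
rigid_beads <- function(com, theta, offsets = popcoupling:::.BEAD_OFFSETS) {
  n <- length(theta)
  pos <- array(0, dim = c(8L, n, 3L))
  for (b in 1:8) {
    pos[b, , 1] <- com[, 1] + offsets[b, 1] * cos(theta) - offsets[b, 2] * sin(theta)
    pos[b, , 2] <- com[, 2] + offsets[b, 1] * sin(theta) + offsets[b, 2] * cos(theta)
    pos[b, , 3] <- com[, 3] + offsets[b, 3]
  }
  bead_trajectories(pos)
}

# evenly spaced spike train at a given rate (deterministic fixture)
regular_spikes <- function(rate_hz, duration_s) {
  seq(0, duration_s - 1e-6, by = 1 / rate_hz)
}
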