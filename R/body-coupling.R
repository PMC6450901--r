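#' @title Body coupling: triggered-average waveforms and surrogate nulls
#' @description Quantifies how strongly a unit's firing relates to body
#'   movement, three ways. BC_M is the SD of the movement-triggered-average
#'   spike rate (MTASR; averaged around movement onsets and cessations,
#'   low-passed at 1.5 Hz, normalized by its mean; BC_M is the mean of the
#'   onset and cessation SDs). BC_S is the SD of the spike-triggered-average
#'   body speed (STABS), processed the same way. BC_D generalizes BC_S to the
#'   27 kinematic aspect series: each spike-triggered waveform is z-scored
#'   per lag against 100 circular-shift surrogate waveforms and BC_D is the
#'   largest across-time SD of the z-scored waveforms over the 27 aspects.
#'   All waveforms cover lags -1..+1 s at 10 ms resolution (201 points).
#'   Significance compares the observed statistic with surrogate values from
#'   circularly time-shifted spike trains (shift at least 30 s), which
#'   preserve spike count and ISI structure.
#' @name body-coupling
NULL

WAVEFORM_HALF_WINDOW <- 100L  # lags in samples at 100 Hz: -1 s .. +1 s
WAVEFORM_CUTOFF_HZ <- 1.5

#' Detect movement onset and cessation events from the body speed
#'
#' The threshold is the whole-session mean speed. An upward crossing that
#' stays on the new side for at least `dwell_s` is an onset; a downward
#' crossing likewise a cessation. Events closer than `refractory_s` to the
#' previous same-type event are suppressed, and events within `edge_s` of the
#' session edges are dropped. Onsets and cessations alternate by construction.
#'
#' @param speed mean body speed series (mm/s).
#' @param sample_rate_hz sampling rate of `speed`.
#' @param refractory_s debounce between same-type events (default 0.5 s).
#' @param dwell_s minimum time on the new side of the threshold (default 0.1 s).
#' @param edge_s guard band at the session edges (default 1 s).
#' @return object of class `event_set`: `onsets`, `cessations` (times in s),
#'   `threshold`, `log`.
#' @export
detect_events <- function(speed, sample_rate_hz = 100, refractory_s = 0.5,
                          dwell_s = 0.1, edge_s = 1) {
  n <- length(speed)
  fs <- sample_rate_hz
  thr <- mean(speed)
  above <- speed > thr
  log <- character(0)
  if (!any(above) || all(above)) {
    log <- c(log, "speed never crosses its mean: no events")
    return(structure(list(onsets = numeric(0), cessations = numeric(0),
                          threshold = thr, log = log), class = "event_set"))
  }
  n_dwell <- max(1L, round(dwell_s * fs))
  runs <- rle(above)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  state <- runs$values[1L]
  ev_time <- numeric(0)
  ev_type <- logical(0)  # TRUE = onset
  for (r in seq_along(runs$lengths)) {
    if (runs$values[r] != state && runs$lengths[r] >= n_dwell) {
      state <- runs$values[r]
      ev_time <- c(ev_time, (starts[r] - 1L) / fs)
      ev_type <- c(ev_type, state)
    }
  }
  # refractory: a same-type event arriving within refractory_s of the last
  # kept one marks a brief excursion; drop it together with its paired
  # opposite event so onsets and cessations keep alternating
  keep <- rep(TRUE, length(ev_time))
  last_on <- -Inf; last_off <- -Inf; skip_next <- FALSE
  for (k in seq_along(ev_time)) {
    if (skip_next) { keep[k] <- FALSE; skip_next <- FALSE; next }
    lt <- if (ev_type[k]) last_on else last_off
    if (ev_time[k] - lt < refractory_s) {
      keep[k] <- FALSE; skip_next <- TRUE
    } else if (ev_type[k]) last_on <- ev_time[k] else last_off <- ev_time[k]
  }
  ev_time <- ev_time[keep]; ev_type <- ev_type[keep]
  dur <- n / fs
  in_bounds <- ev_time >= edge_s & ev_time <= dur - edge_s
  if (any(!in_bounds)) {
    log <- c(log, sprintf("dropped %d event(s) within %g s of session edges",
                          sum(!in_bounds), edge_s))
  }
  ev_time <- ev_time[in_bounds]; ev_type <- ev_type[in_bounds]
  structure(list(onsets = ev_time[ev_type], cessations = ev_time[!ev_type],
                 threshold = thr, log = log),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d onsets, %d cessations (threshold %.2f)\n",
              length(x$onsets), length(x$cessations), x$threshold))
  invisible(x)
}

# nearest-sample index of a time on the kinematic grid
.sample_index <- function(times_s, fs, n) {
  pmin(pmax(round(times_s * fs) + 1L, 1L), n)
}

# spike/event counts on the kinematic sample grid
.counts_per_sample <- function(times_s, fs, n) {
  tabulate(.sample_index(times_s, fs, n), nbins = n)
}

# observed triggered average: mean of series[idx + lag] over triggers with
# full +-n_lag windows. Returns NULL if no trigger has a full window.
.sta_observed <- function(series, trig_idx, n_lag = WAVEFORM_HALF_WINDOW) {
  n <- length(series)
  trig_idx <- trig_idx[trig_idx > n_lag & trig_idx <= n - n_lag]
  if (length(trig_idx) == 0L) return(NULL)
  lags <- seq(-n_lag, n_lag)
  idx <- outer(trig_idx, lags, `+`)
  vals <- series[idx]
  dim(vals) <- dim(idx)
  list(values = colMeans(vals), n_triggers = length(trig_idx))
}

# full circular cross-correlation cc[m] = sum_k trig[k] * series[(k+m-1) mod n + 1]
# returned as a closure-friendly vector: cc_at(m) = cc[[(m mod n) + 1]]
.circular_crosscorr <- function(trig_counts, series) {
  n <- length(series)
  stopifnot(length(trig_counts) == n)
  cc <- Re(stats::fft(Conj(stats::fft(trig_counts)) * stats::fft(series),
                      inverse = TRUE)) / n
  cc
}

# slice surrogate triggered averages out of a circular cross-correlation.
# sign = +1 when the triggers are shifted forward by `offsets` (triggered
# average samples the series at lag + offset); sign = -1 when the series
# itself is the shifted object (lag - offset).
.sta_slices <- function(cc, n_triggers, offsets, sign,
                        n_lag = WAVEFORM_HALF_WINDOW) {
  n <- length(cc)
  lags <- seq(-n_lag, n_lag)
  vapply(offsets, function(o) {
    m <- (sign * o + lags) %% n
    cc[m + 1L] / n_triggers
  }, numeric(2L * n_lag + 1L))  # (201 x n_offsets)
}

# low-pass + optional mean normalization of a 201-point waveform
.finish_waveform <- function(values, fs = 100, cutoff = WAVEFORM_CUTOFF_HZ,
                             normalize = TRUE) {
  filt <- lowpass_zero_phase(values, cutoff, fs)
  if (!normalize) {
    return(list(values = filt, sd = stats::sd(filt), degenerate = FALSE))
  }
  m <- mean(filt)
  if (abs(m) < 1e-12) {
    return(list(values = filt, sd = 0, degenerate = TRUE))
  }
  norm <- filt / m
  list(values = norm, sd = stats::sd(norm), degenerate = FALSE)
}

.waveform <- function(values, n_triggers, normalized, fs = 100) {
  structure(list(lags_s = seq(-WAVEFORM_HALF_WINDOW, WAVEFORM_HALF_WINDOW) / fs,
                 values = values, n_triggers = n_triggers,
                 normalized = normalized),
            class = "triggered_waveform")
}

#' @export
print.triggered_waveform <- function(x, ...) {
  cat(sprintf("<triggered_waveform> %d lags, %d triggers%s\n",
              length(x$lags_s), x$n_triggers,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Movement-triggered-average spike rate and BC_M
#'
#' The unit's spike rate in 10 ms steps for lags within +-1 s of each movement
#' onset (and, separately, cessation), averaged over triggers, low-pass
#' filtered at 1.5 Hz and normalized by its mean. BC_M is the mean of the
#' onset-waveform SD and the cessation-waveform SD. Triggers whose window
#' crosses a session edge are dropped.
#'
#' @param spike_times one unit's spike times (s).
#' @param events an [detect_events()] result.
#' @param n_samples number of kinematic samples in the session.
#' @param sample_rate_hz kinematic sampling rate (default 100).
#' @param min_events minimum onsets and cessations required (default 5).
#' @return list with `onset`, `cessation` ([`triggered_waveform`]s or `NULL`),
#'   `bc_m`, `degenerate`, `flag`.
#' @export
mtasr <- function(spike_times, events, n_samples, sample_rate_hz = 100,
                  min_events = 5L) {
  fs <- sample_rate_hz
  counts <- .counts_per_sample(spike_times, fs, n_samples)
  one <- function(trig_times) {
    trig_idx <- .sample_index(trig_times, fs, n_samples)
    sta <- .sta_observed(counts, trig_idx)
    if (is.null(sta) || sta$n_triggers < min_events) return(NULL)
    rate <- sta$values / (1 / fs)   # spikes per trigger per 10 ms -> Hz
    fin <- .finish_waveform(rate)
    list(wave = .waveform(fin$values, sta$n_triggers, normalized = TRUE),
         sd = fin$sd, degenerate = fin$degenerate)
  }
  on <- one(events$onsets)
  off <- one(events$cessations)
  if (is.null(on) || is.null(off)) {
    return(list(onset = if (is.null(on)) NULL else on$wave,
                cessation = if (is.null(off)) NULL else off$wave,
                bc_m = NA_real_, degenerate = FALSE,
                flag = "insufficient_events"))
  }
  list(onset = on$wave, cessation = off$wave,
       bc_m = (on$sd + off$sd) / 2,
       degenerate = on$degenerate || off$degenerate,
       flag = if (on$degenerate || off$degenerate) "degenerate" else "ok")
}

#' Spike-triggered-average body speed and BC_S
#'
#' The body speed for lags within +-1 s of each spike, averaged over spikes,
#' low-pass filtered at 1.5 Hz and normalized by its mean; BC_S is the SD of
#' the result. Spikes whose window crosses a session edge are dropped.
#'
#' @param spike_times one unit's spike times (s).
#' @param speed mean body speed series (mm/s).
#' @param sample_rate_hz kinematic sampling rate (default 100).
#' @param min_spikes minimum spikes with full windows (default 50).
#' @return list with `waveform`, `bc_s`, `degenerate`, `flag`.
#' @export
stabs <- function(spike_times, speed, sample_rate_hz = 100, min_spikes = 50L) {
  fs <- sample_rate_hz
  n <- length(speed)
  idx <- .sample_index(spike_times, fs, n)
  sta <- .sta_observed(speed, idx)
  if (is.null(sta) || sta$n_triggers < min_spikes) {
    return(list(waveform = NULL, bc_s = NA_real_, degenerate = FALSE,
                flag = "insufficient_spikes"))
  }
  fin <- .finish_waveform(sta$values)
  list(waveform = .waveform(fin$values, sta$n_triggers, normalized = TRUE),
       bc_s = fin$sd, degenerate = fin$degenerate,
       flag = if (fin$degenerate) "degenerate" else "ok")
}

#' Circular-shift surrogate spike trains
#'
#' Each surrogate shifts all spike times by one uniform random offset drawn
#' from `[min_offset_s, duration_s - min_offset_s]`, modulo the session
#' duration. Spike count and inter-spike-interval structure are preserved.
#' Consumes the current RNG stream (seed upstream with `set.seed()`).
#'
#' @param spike_times one unit's spike times (s).
#' @param duration_s session duration (must exceed `2 * min_offset_s`).
#' @param n_surrogates number of surrogate trains.
#' @param min_offset_s minimum shift (default 30 s).
#' @return list of numeric vectors (sorted shifted spike times).
#' @export
shift_surrogate <- function(spike_times, duration_s, n_surrogates,
                            min_offset_s = 30) {
  if (duration_s <= 2 * min_offset_s) {
    stop("session too short for circular-shift surrogates")
  }
  offs <- stats::runif(n_surrogates, min_offset_s, duration_s - min_offset_s)
  lapply(offs, function(o) sort((spike_times + o) %% duration_s))
}

# integer sample offsets for the fast (slice-based) surrogate path
.draw_offsets <- function(n_samples, n_surrogates, sample_rate_hz = 100,
                          min_offset_s = 30) {
  lo <- round(min_offset_s * sample_rate_hz)
  if (n_samples <= 2L * lo) stop("session too short for circular-shift surrogates")
  sample.int(n_samples - 2L * lo + 1L, n_surrogates, replace = TRUE) + lo - 1L
}

#' Surrogate significance at the 95% criterion
#'
#' A body-coupling value is significant when it is strictly higher than at
#' least 95% of its surrogate values; ties at the threshold do not count.
#'
#' @param bc observed body-coupling value.
#' @param surrogate_bc numeric vector of surrogate values.
#' @param level criterion level (default 0.95).
#' @return logical flag.
#' @export
significance <- function(bc, surrogate_bc, level = 0.95) {
  if (is.na(bc)) return(NA)
  mean(surrogate_bc < bc) >= level
}

#' BC_S with its circular-shift surrogate null
#'
#' @inheritParams stabs
#' @param n_surrogates number of surrogates (default 1000).
#' @return `stabs()` result plus `surrogate_bc_s` and `significant`.
#' @export
body_coupling_stabs <- function(spike_times, speed, sample_rate_hz = 100,
                                n_surrogates = 1000L, min_spikes = 50L) {
  obs <- stabs(spike_times, speed, sample_rate_hz, min_spikes)
  if (is.na(obs$bc_s)) {
    obs$surrogate_bc_s <- numeric(0); obs$significant <- NA
    return(obs)
  }
  fs <- sample_rate_hz
  n <- length(speed)
  counts <- .counts_per_sample(spike_times, fs, n)
  cc <- .circular_crosscorr(counts, speed)
  offs <- .draw_offsets(n, n_surrogates, fs)
  slices <- .sta_slices(cc, sum(counts), offs, sign = +1L)
  obs$surrogate_bc_s <- apply(slices, 2L, function(w) .finish_waveform(w)$sd)
  obs$significant <- significance(obs$bc_s, obs$surrogate_bc_s)
  obs
}

#' BC_M with its circular-shift surrogate null
#'
#' @inheritParams mtasr
#' @param n_surrogates number of surrogates (default 1000).
#' @return `mtasr()` result plus `surrogate_bc_m` and `significant`.
#' @export
body_coupling_mtasr <- function(spike_times, events, n_samples,
                                sample_rate_hz = 100, n_surrogates = 1000L,
                                min_events = 5L) {
  obs <- mtasr(spike_times, events, n_samples, sample_rate_hz, min_events)
  if (is.na(obs$bc_m)) {
    obs$surrogate_bc_m <- numeric(0); obs$significant <- NA
    return(obs)
  }
  fs <- sample_rate_hz
  counts <- .counts_per_sample(spike_times, fs, n_samples)
  offs <- .draw_offsets(n_samples, n_surrogates, fs)
  surr_sd <- function(trig_times) {
    trig <- .counts_per_sample(trig_times, fs, n_samples)
    cc <- .circular_crosscorr(trig, counts)
    # shifting the spikes (the series here) moves the waveform to lag - offset
    slices <- .sta_slices(cc, sum(trig), offs, sign = -1L)
    apply(slices, 2L, function(w) .finish_waveform(w * fs)$sd)
  }
  sd_on <- surr_sd(events$onsets)
  sd_off <- surr_sd(events$cessations)
  obs$surrogate_bc_m <- (sd_on + sd_off) / 2
  obs$significant <- significance(obs$bc_m, obs$surrogate_bc_m)
  obs
}

#' BC_D: detailed body coupling over the 27 movement aspects
#'
#' For each aspect, the spike-triggered average waveform (+-1 s, 10 ms) is
#' low-pass filtered at 1.5 Hz and z-scored per lag against `n_surrogates`
#' circular-shift surrogate waveforms processed identically. The per-aspect
#' score is the SD across lags of the z-scored waveform; BC_D is the maximum
#' score and `best_aspect_index` its argmax. Lags where the surrogate SD is
#' zero get z = 0 (logged).
#'
#' @param spike_times one unit's spike times (s).
#' @param kin a [compute_aspects()] result.
#' @param n_surrogates surrogate count for z-scoring (default 100).
#' @param min_spikes minimum spikes with full windows (default 50).
#' @return list with `bc_d`, `best_aspect_index`, `scores` (27), `z_waveforms`
#'   (27 x 201), `flag`, `log`.
#' @export
bcd <- function(spike_times, kin, n_surrogates = 100L, min_spikes = 50L) {
  fs <- kin$sample_rate_hz
  n <- ncol(kin$aspects)
  idx <- .sample_index(spike_times, fs, n)
  counts <- .counts_per_sample(spike_times, fs, n)
  probe <- .sta_observed(kin$aspects[1, ], idx)
  if (is.null(probe) || probe$n_triggers < min_spikes) {
    return(list(bc_d = NA_real_, best_aspect_index = NA_integer_,
                scores = rep(NA_real_, 27L), z_waveforms = NULL,
                flag = "insufficient_spikes", log = character(0)))
  }
  offs <- .draw_offsets(n, n_surrogates, fs)
  log <- character(0)
  n_lags <- 2L * WAVEFORM_HALF_WINDOW + 1L
  z_wave <- matrix(NA_real_, 27L, n_lags)
  scores <- numeric(27L)
  for (a in 1:27) {
    series <- kin$aspects[a, ]
    obs <- .finish_waveform(.sta_observed(series, idx)$values,
                            normalize = FALSE)$values
    cc <- .circular_crosscorr(counts, series)
    slices <- .sta_slices(cc, sum(counts), offs, sign = +1L)
    surr <- apply(slices, 2L, function(w) {
      .finish_waveform(w, normalize = FALSE)$values
    })  # n_lags x n_surrogates
    mu <- rowMeans(surr)
    sdv <- apply(surr, 1L, stats::sd)
    z <- (obs - mu) / sdv
    zero_sd <- sdv < 1e-12
    if (any(zero_sd)) {
      z[zero_sd] <- 0
      log <- c(log, sprintf("aspect %d: %d lag(s) with zero surrogate SD",
                            a, sum(zero_sd)))
    }
    z_wave[a, ] <- z
    scores[a] <- stats::sd(z)
  }
  best <- which.max(scores)
  list(bc_d = scores[best], best_aspect_index = best, scores = scores,
       z_waveforms = z_wave, flag = "ok", log = log)
}

#' Export a triggered waveform to CSV (`lag_s,value`)
#' @param wave a `triggered_waveform`.
#' @param path output path.
#' @export
export_waveform <- function(wave, path) {
  utils::write.csv(data.frame(lag_s = wave$lags_s, value = wave$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
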