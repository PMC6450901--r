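#' @title Session data model and delimited-text I/O
#' @description Constructors and validators for the core containers: a set of
#'   spike trains, a block of 3D bead trajectories from motion tracking, and a
#'   session bundling the two with condition metadata; plus readers/writers for
#'   the plain-text formats and the unit/session exclusion rules.
#' @name data-model
NULL

#' Canonical anatomical bead order
#'
#' Eight reflective beads along the animal's body, head to tail-base.
#' @export
BEAD_LABELS <- c("head", "neck_base", "back_1", "back_2", "back_3", "back_4",
                 "hips", "tail_base")

#' Construct a spike train set
#'
#' @param spike_times named list of numeric vectors, spike times in seconds
#'   from session start (one element per unit). Times are sorted on input.
#' @param duration_s session duration in seconds; all spikes must fall in
#'   `[0, duration_s)`.
#' @return an object of class `spike_train_set` with fields `unit_ids`,
#'   `spike_times`, `duration_s`.
#' @export
spike_train_set <- function(spike_times, duration_s) {
  if (!is.list(spike_times) || length(spike_times) == 0L) {
    stop("spike_times must be a non-empty named list")
  }
  if (is.null(names(spike_times)) || any(!nzchar(names(spike_times)))) {
    stop("every unit needs a label")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("duration_s must be a positive scalar")
  }
  spike_times <- lapply(spike_times, function(t) {
    t <- as.numeric(t)
    if (anyNA(t)) stop("spike times contain NA")
    if (any(t < 0)) stop("spike times must be non-negative")
    if (any(t >= duration_s)) stop("spike times must be strictly within [0, duration_s)")
    sort(t)
  })
  structure(list(unit_ids = names(spike_times),
                 spike_times = spike_times,
                 duration_s = duration_s),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d units, %.1f s, %d spikes\n",
              length(x$unit_ids), x$duration_s,
              sum(lengths(x$spike_times))))
  invisible(x)
}

#' Construct bead trajectories
#'
#' @param positions numeric array `beads x samples x 3`, positions in mm.
#' @param bead_labels 8 labels in anatomical order (default [BEAD_LABELS]).
#' @param sample_rate_hz sampling rate (100 Hz for the tracking system).
#' @param start_time_s time of the first sample.
#' @return object of class `bead_trajectories`.
#' @export
bead_trajectories <- function(positions, bead_labels = BEAD_LABELS,
                              sample_rate_hz = 100, start_time_s = 0) {
  if (length(dim(positions)) != 3L || dim(positions)[1] != 8L ||
      dim(positions)[3] != 3L) {
    stop("positions must be an 8 x samples x 3 array")
  }
  if (length(bead_labels) != 8L) stop("exactly 8 bead labels required")
  if (any(!is.finite(positions))) stop("positions must be finite after gap-fill")
  structure(list(positions = positions,
                 bead_labels = bead_labels,
                 sample_rate_hz = sample_rate_hz,
                 start_time_s = start_time_s),
            class = "bead_trajectories")
}

#' @export
print.bead_trajectories <- function(x, ...) {
  cat(sprintf("<bead_trajectories> 8 beads x %d samples @ %g Hz\n",
              dim(x$positions)[2], x$sample_rate_hz))
  invisible(x)
}

#' Duration covered by a bead trajectory block, in seconds
#' @param beads a `bead_trajectories` object.
#' @export
beads_duration <- function(beads) {
  dim(beads$positions)[2] / beads$sample_rate_hz
}

#' Construct a recording session
#'
#' A session bundles one recording's spike trains with (optionally) its bead
#' trajectories and the pharmacological condition metadata. When beads are
#' present, the spike duration and motion duration must agree within one
#' motion sample.
#'
#' @param session_id identifier string.
#' @param spikes a [spike_train_set()].
#' @param beads a [bead_trajectories()] or `NULL` for model-only sessions.
#' @param condition list with elements `drug` (one of "none", "muscimol",
#'   "PTZ", "bicuculline"), `route` ("systemic" or "local"), `dose`.
#' @return object of class `session`.
#' @export
session <- function(session_id, spikes, beads = NULL,
                    condition = list(drug = "none", route = NA, dose = NA)) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (!is.null(beads)) {
    stopifnot(inherits(beads, "bead_trajectories"))
    tol <- 1 / beads$sample_rate_hz
    if (abs(beads_duration(beads) - spikes$duration_s) > tol + 1e-9) {
      stop("spike duration and bead duration disagree by more than one motion sample")
    }
  }
  drug <- condition$drug %||% "none"
  if (!drug %in% c("none", "muscimol", "PTZ", "bicuculline")) {
    stop("unknown drug condition: ", drug)
  }
  structure(list(session_id = as.character(session_id),
                 condition = condition,
                 spikes = spikes,
                 beads = beads,
                 excluded = FALSE),
            class = "session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session %s> %d units, %.1f s, beads: %s, drug: %s%s\n",
              x$session_id, length(x$spikes$unit_ids), x$spikes$duration_s,
              if (is.null(x$beads)) "absent" else "present",
              x$condition$drug %||% "none",
              if (isTRUE(x$excluded)) " [EXCLUDED]" else ""))
  invisible(x)
}

#' Read a spike file
#'
#' Expects a CSV with header `unit_id,spike_time_s`.
#'
#' @param path file path.
#' @param duration_s session duration; if `NULL`, the maximum spike time is
#'   rounded up to the next whole second.
#' @return a [spike_train_set()].
#' @export
read_spikes <- function(path, duration_s = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("spike file is empty: ", path)
  if (!all(c("unit_id", "spike_time_s") %in% names(df))) {
    stop("spike file must have columns unit_id, spike_time_s")
  }
  tms <- suppressWarnings(as.numeric(df$spike_time_s))
  bad <- which(!is.finite(tms) | tms < 0)
  if (length(bad) > 0L) {
    stop(sprintf("invalid spike time at line %d of %s: %s",
                 bad[1L] + 1L, path, df$spike_time_s[bad[1L]]))
  }
  if (is.null(duration_s)) duration_s <- ceiling(max(tms) + 1e-9)
  spike_train_set(split(tms, factor(df$unit_id, levels = unique(df$unit_id))),
                  duration_s)
}

#' Write a spike file
#' @param spikes a [spike_train_set()].
#' @param path output path.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(
    unit_id = rep(spikes$unit_ids, lengths(spikes$spike_times)),
    spike_time_s = unlist(spikes$spike_times, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bead trajectory file
#'
#' Expects a long CSV `time_s,bead_label,x_mm,y_mm,z_mm` on a uniform 100 Hz
#' grid. Gaps (missing samples) of at most `max_gap_s` are filled by linear
#' interpolation; longer gaps are an error.
#'
#' @param path file path.
#' @param sample_rate_hz expected sampling rate (default 100).
#' @param max_gap_s longest gap that is interpolated (default 0.1 s).
#' @return a [bead_trajectories()].
#' @export
read_beads <- function(path, sample_rate_hz = 100, max_gap_s = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "bead_label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("bead file must have columns ", paste(need, collapse = ", "))
  }
  missing_beads <- setdiff(BEAD_LABELS, unique(df$bead_label))
  if (length(missing_beads) > 0L) {
    stop("missing bead label(s): ", paste(missing_beads, collapse = ", "))
  }
  t0 <- min(df$time_s)
  t1 <- max(df$time_s)
  dt <- 1 / sample_rate_hz
  grid <- seq(0, round((t1 - t0) / dt)) * dt + t0
  n <- length(grid)
  pos <- array(NA_real_, dim = c(8L, n, 3L))
  for (b in seq_along(BEAD_LABELS)) {
    sub <- df[df$bead_label == BEAD_LABELS[b], ]
    idx <- (sub$time_s - t0) / dt
    if (any(abs(idx - round(idx)) > 1e-6 * sample_rate_hz)) {
      stop("non-uniform sampling for bead ", BEAD_LABELS[b])
    }
    idx <- round(idx) + 1L
    for (k in 1:3) {
      v <- rep(NA_real_, n)
      v[idx] <- sub[[need[k + 2L]]]
      miss <- is.na(v)
      if (any(miss)) {
        runs <- rle(miss)
        if (runs$values[1L] || runs$values[length(runs$values)]) {
          stop("gap too long: bead ", BEAD_LABELS[b], " missing at a session edge")
        }
        if (any(runs$lengths[runs$values] * dt > max_gap_s + 1e-9)) {
          stop("gap too long for bead ", BEAD_LABELS[b])
        }
        v <- stats::approx(grid[!miss], v[!miss], xout = grid)$y
      }
      pos[b, , k] <- v
    }
  }
  bead_trajectories(pos, BEAD_LABELS, sample_rate_hz, start_time_s = t0)
}

#' Write a bead trajectory file
#' @param beads a [bead_trajectories()].
#' @param path output path.
#' @export
write_beads <- function(beads, path) {
  n <- dim(beads$positions)[2]
  tms <- beads$start_time_s + (seq_len(n) - 1L) / beads$sample_rate_hz
  df <- data.frame(
    time_s = rep(tms, times = 8L),
    bead_label = rep(beads$bead_labels, each = n),
    x_mm = as.vector(t(beads$positions[, , 1])),
    y_mm = as.vector(t(beads$positions[, , 2])),
    z_mm = as.vector(t(beads$positions[, , 3])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the unit-rate and unit-count exclusion rules
#'
#' Units with whole-session spike rate below `min_rate_hz` are removed first;
#' if fewer than `min_units` units survive, the whole session is flagged
#' excluded. The log records every removal with its reason. Idempotent.
#'
#' @param sess a [session()].
#' @param min_rate_hz minimum spike rate (default 0.5 Hz).
#' @param min_units minimum number of retained units (default 5).
#' @return list with elements `session` (units removed, `excluded` flag set),
#'   `excluded` (logical) and `log` (character vector, one line per action).
#' @export
apply_exclusions <- function(sess, min_rate_hz = 0.5, min_units = 5L) {
  stopifnot(inherits(sess, "session"))
  dur <- sess$spikes$duration_s
  rates <- lengths(sess$spikes$spike_times) / dur
  keep <- rates >= min_rate_hz
  log <- sprintf("excluded unit %s: rate %.4f Hz < %.2f Hz",
                 sess$spikes$unit_ids[!keep], rates[!keep], min_rate_hz)
  if (any(keep)) {
    sess$spikes$spike_times <- sess$spikes$spike_times[keep]
    sess$spikes$unit_ids <- sess$spikes$unit_ids[keep]
  } else {
    sess$spikes$spike_times <- sess$spikes$spike_times[0]
    sess$spikes$unit_ids <- character(0)
  }
  excluded <- sum(keep) < min_units
  if (excluded) {
    log <- c(log, sprintf("excluded session %s: %d units < %d",
                          sess$session_id, sum(keep), min_units))
  }
  sess$excluded <- excluded
  list(session = sess, excluded = excluded, log = log)
}

#' Write a coupling table
#'
#' One row per retained unit with its session id, rate, population coupling
#' and the three body-coupling statistics with significance flags.
#' @param table data.frame as produced by [analyze_session()].
#' @param path output path.
#' @export
write_coupling_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coupling table written by [write_coupling_table()]
#' @param path file path.
#' @export
read_coupling_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an exclusion log (one line per action)
#' @param log character vector.
#' @param path output path.
#' @export
write_exclusion_log <- function(log, path) {
  writeLines(log, path)
  invisible(path)
}
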