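#' @title Population coupling of spike trains
#' @description Spike-count binning and the per-unit population-coupling
#'   statistic: the spike-weighted average of the mean-subtracted summed
#'   counts of all other units,
#'   \deqn{C_{pop,i} = \frac{1}{N_i} \sum_{t=1}^{T} f_i(t) P_i(t), \qquad
#'         P_i(t) = \sum_{j \ne i} (f_j(t) - \mu_j),}
#'   where \eqn{f_i(t)} is the spike count of unit \eqn{i} in bin \eqn{t},
#'   \eqn{N_i} its total spike count and \eqn{\mu_j} the mean count of unit
#'   \eqn{j}. Dimensionless; positive for units that fire with the crowd,
#'   negative for anticorrelated units.
#' @name population-coupling
NULL

#' Bin spike trains into a unit-by-bin count matrix
#'
#' Half-open bins `[t, t+bin_width_s)`; the trailing partial bin is discarded.
#'
#' @param spikes a [spike_train_set()].
#' @param bin_width_s bin width in seconds (default 0.25 s; the robustness set
#'   used elsewhere is 0.25, 0.1, 0.05, 0.01 s).
#' @return object of class `binned_counts`: `counts` (units x bins integer
#'   matrix), `bin_width_s`, `n_bins`, `unit_ids`.
#' @export
bin_spikes <- function(spikes, bin_width_s = 0.25) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (!is.numeric(bin_width_s) || bin_width_s <= 0) {
    stop("bin_width_s must be positive")
  }
  n_bins <- floor(spikes$duration_s / bin_width_s + 1e-9)
  if (n_bins < 1L) stop("bin width larger than session duration")
  counts <- t(vapply(spikes$spike_times, function(t) {
    idx <- floor(t / bin_width_s) + 1L
    tabulate(idx[idx <= n_bins], nbins = n_bins)
  }, integer(n_bins)))
  structure(list(counts = counts, bin_width_s = bin_width_s,
                 n_bins = n_bins, unit_ids = spikes$unit_ids),
            class = "binned_counts")
}

# core of Eq. 1 / Eq. 2 on a count matrix; rows with zero spikes get NA
.cpop_core <- function(f) {
  mu <- rowMeans(f)
  dev <- f - mu
  tot_dev <- colSums(dev)
  n_i <- rowSums(f)
  # P_i(t) = total deviation minus unit i's own deviation
  num <- rowSums(f * (matrix(tot_dev, nrow(f), ncol(f), byrow = TRUE) - dev))
  ifelse(n_i > 0, num / n_i, NA_real_)
}

#' Population coupling per unit
#'
#' @param b a [bin_spikes()] result (or any `binned_counts`).
#' @param allow_zero_units if `FALSE` (default) a unit with no spikes is an
#'   error (it should have been excluded upstream); if `TRUE` such units get
#'   `NA`.
#' @return object of class `population_coupling`: `c_pop` (named numeric),
#'   `bin_width_s`, `n_units`, `n_spikes`, `mean_count`.
#' @export
population_coupling <- function(b, allow_zero_units = FALSE) {
  stopifnot(inherits(b, "binned_counts"))
  f <- b$counts
  if (nrow(f) < 2L) stop("population coupling needs at least 2 units")
  n_i <- rowSums(f)
  if (!allow_zero_units && any(n_i == 0)) {
    stop("unit(s) with zero spikes: ",
         paste(b$unit_ids[n_i == 0], collapse = ", "),
         " (exclude before computing population coupling)")
  }
  c_pop <- .cpop_core(f)
  names(c_pop) <- b$unit_ids
  structure(list(c_pop = c_pop, bin_width_s = b$bin_width_s,
                 n_units = nrow(f), n_spikes = n_i,
                 mean_count = rowMeans(f)),
            class = "population_coupling")
}

#' @export
print.population_coupling <- function(x, ...) {
  cat(sprintf("<population_coupling> %d units @ %g s bins; mean C_pop %.3f\n",
              x$n_units, x$bin_width_s, mean(x$c_pop, na.rm = TRUE)))
  invisible(x)
}

#' Population coupling recomputed on two bin partitions
#'
#' The statistic is evaluated independently on the bins where `mask` is `TRUE`
#' and where it is `FALSE` (means and spike totals recomputed per partition).
#' A partition with fewer than `min_bins` bins is undefined (`NULL`); a unit
#' silent within a partition has its value set to `NA` and logged.
#'
#' @param b a `binned_counts`.
#' @param mask logical vector, one element per bin.
#' @param min_bins minimum bins for a partition to be defined (default 10).
#' @return list with `in_mask`, `out_mask` (each a `population_coupling` or
#'   `NULL`) and `log`.
#' @export
split_population_coupling <- function(b, mask, min_bins = 10L) {
  stopifnot(inherits(b, "binned_counts"))
  if (length(mask) != b$n_bins) stop("mask length must equal n_bins")
  log <- character(0)
  part <- function(keep) {
    if (sum(keep) < min_bins) return(NULL)
    sub <- b
    sub$counts <- b$counts[, keep, drop = FALSE]
    sub$n_bins <- sum(keep)
    silent <- rowSums(sub$counts) == 0
    if (any(silent)) {
      log <<- c(log, sprintf("unit %s silent in partition: C_pop undefined",
                             b$unit_ids[silent]))
    }
    population_coupling(sub, allow_zero_units = TRUE)
  }
  list(in_mask = part(mask), out_mask = part(!mask), log = log)
}

#' Label each bin as rest or motion from the mean body speed
#'
#' A bin is "motion" when the mean body speed within the bin exceeds the
#' whole-session mean speed, "rest" otherwise.
#'
#' @param b a `binned_counts`.
#' @param speed mean body speed series (mm/s).
#' @param sample_rate_hz sampling rate of `speed`.
#' @return logical vector of length `n_bins`; `TRUE` = motion.
#' @export
rest_motion_mask <- function(b, speed, sample_rate_hz = 100) {
  tms <- (seq_along(speed) - 1L) / sample_rate_hz
  bin <- floor(tms / b$bin_width_s) + 1L
  ok <- bin <= b$n_bins
  bin_mean <- as.numeric(tapply(speed[ok], factor(bin[ok], levels = seq_len(b$n_bins)),
                                mean))
  bin_mean[is.na(bin_mean)] <- 0
  bin_mean > mean(speed)
}

#' Population coupling of rest vs motion bins
#'
#' @param b a `binned_counts`.
#' @param speed mean body speed series.
#' @param sample_rate_hz sampling rate of `speed`.
#' @return list with `rest`, `motion` (each `population_coupling` or `NULL`)
#'   and `log`.
#' @export
rest_motion_coupling <- function(b, speed, sample_rate_hz = 100) {
  mask <- rest_motion_mask(b, speed, sample_rate_hz)
  s <- split_population_coupling(b, mask)
  list(motion = s$in_mask, rest = s$out_mask, log = s$log)
}

#' Population coupling of the two half-sessions
#'
#' First `floor(T/2)` bins versus the remainder.
#' @param b a `binned_counts`.
#' @return list with `first`, `second` and `log`.
#' @export
half_session_coupling <- function(b) {
  h <- floor(b$n_bins / 2)
  mask <- seq_len(b$n_bins) <= h
  s <- split_population_coupling(b, mask, min_bins = 1L)
  list(first = s$in_mask, second = s$out_mask, log = s$log)
}
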