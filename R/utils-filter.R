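#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) low-pass filtering with a Butterworth design.
#' The series is padded by odd reflection at both ends before filtering so that
#' the zero initial conditions of the underlying recursive filter do not leak
#' edge transients into the result; a constant series passes through unchanged
#' (unit DC gain).
#'
#' @param x numeric vector to filter.
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist rate.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, cutoff_hz, fs, order = 4L) {
  n <- length(x)
  if (n < 2L) stop("series too short to filter")
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff_hz must lie in (0, fs/2)")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # remove the mean first: the recursive filter's zero initial conditions
  # otherwise leak a transient proportional to the absolute signal level
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1L, max(3L * order, ceiling(10 * fs / cutoff_hz)))
  left <- 2 * xc[1L] - xc[seq(pad + 1L, 2L)]
  right <- 2 * xc[n] - xc[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, xc, right))
  y[seq(pad + 1L, pad + n)] + mu
}

#' @keywords internal
.unwrap <- function(theta) {
  # phase unwrapping across the +-pi boundary
  d <- diff(theta)
  jumps <- round(d / (2 * pi))
  theta - c(0, cumsum(jumps)) * 2 * pi
}

#' @keywords internal
.central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 3L) stop("series too short to differentiate")
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d
}
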