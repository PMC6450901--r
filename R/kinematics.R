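#' @title Kinematic feature extraction from bead trajectories
#' @description Turns the 8-bead 3D trajectories into per-bead speeds, the
#'   mean body speed, and the 27 movement-aspect series used for detailed body
#'   coupling: (1) center-of-mass speed, (2) left-right turning angular speed,
#'   (3) up-down rearing angular speed, (4-27) the three orthogonal components
#'   of each bead's velocity relative to the body axis (rostrocaudal,
#'   right-left, up-down), ordered bead-major.
#' @name kinematics
NULL

#' Smooth bead positions and differentiate
#'
#' Each coordinate is low-pass filtered (zero-phase Butterworth, default
#' cutoff 5 Hz) and then differentiated by central differences. Speed is the
#' Euclidean norm of the velocity.
#'
#' @param beads a [bead_trajectories()].
#' @param cutoff_hz low-pass cutoff (default 5 Hz).
#' @return list with `positions` (smoothed, beads x samples x 3), `velocities`
#'   (same shape, mm/s), `speeds` (beads x samples, mm/s), `sample_rate_hz`.
#' @export
preprocess_positions <- function(beads, cutoff_hz = 5) {
  stopifnot(inherits(beads, "bead_trajectories"))
  fs <- beads$sample_rate_hz
  n <- dim(beads$positions)[2]
  if (n < fs) stop("need at least 1 s of bead data")
  pos <- beads$positions
  vel <- array(0, dim = dim(pos))
  for (b in 1:8) {
    for (k in 1:3) {
      pos[b, , k] <- lowpass_zero_phase(pos[b, , k], cutoff_hz, fs)
      vel[b, , k] <- .central_diff(pos[b, , k], fs)
    }
  }
  speeds <- sqrt(vel[, , 1]^2 + vel[, , 2]^2 + vel[, , 3]^2)
  list(positions = pos, velocities = vel, speeds = speeds, sample_rate_hz = fs)
}

#' Mean body speed
#'
#' Pointwise arithmetic mean of the eight bead speeds.
#' @param k result of [preprocess_positions()] or [compute_aspects()].
#' @return numeric vector, mm/s.
#' @export
mean_body_speed <- function(k) {
  if (!is.null(k$mean_body_speed)) return(k$mean_body_speed)
  colMeans(k$speeds)
}

# leading principal axis of three centered 3D points, vectorized over samples.
# q1,q2,q3: n x 3 matrices of centered points; v0: n x 3 initial direction.
.principal_axis3 <- function(q1, q2, q3, v0, n_iter = 12L) {
  v <- v0 / pmax(sqrt(rowSums(v0^2)), 1e-12)
  for (it in seq_len(n_iter)) {
    # C v = sum_k q_k (q_k . v)
    w <- q1 * rowSums(q1 * v) + q2 * rowSums(q2 * v) + q3 * rowSums(q3 * v)
    nrm <- sqrt(rowSums(w^2))
    ok <- nrm > 1e-12
    v[ok, ] <- w[ok, ] / nrm[ok]
  }
  v
}

#' Extract the 27 movement aspects
#'
#' The center of mass (COM) is the equal-weight mean of the eight beads. The
#' body vector is the best-fit 3D line through the COM, the head bead and the
#' neck-base bead (principal axis of the three centered points), oriented so
#' the head bead has positive projection. The turning angle is the azimuth of
#' the body vector's horizontal projection relative to the lab +x axis
#' (unwrapped); the rearing angle is its elevation above horizontal; both are
#' differentiated to angular velocities. The 24 relative components are each
#' bead's velocity minus the COM velocity, projected on the body-frame axes
#' (rostrocaudal = unit horizontal projection of the body vector, right-left =
#' its horizontal perpendicular, up-down = vertical).
#'
#' @param beads a [bead_trajectories()].
#' @param cutoff_hz low-pass cutoff for [preprocess_positions()].
#' @return object of class `kinematics_series` with `sample_rate_hz`,
#'   `bead_speeds` (8 x samples), `mean_body_speed`, `aspects` (27 x samples),
#'   `aspect_names`, `log`.
#' @export
compute_aspects <- function(beads, cutoff_hz = 5) {
  pre <- preprocess_positions(beads, cutoff_hz)
  fs <- pre$sample_rate_hz
  n <- dim(pre$positions)[2]
  log <- character(0)

  pmat <- function(b) cbind(pre$positions[b, , 1], pre$positions[b, , 2],
                            pre$positions[b, , 3])
  vmat <- function(b) cbind(pre$velocities[b, , 1], pre$velocities[b, , 2],
                            pre$velocities[b, , 3])

  com <- (Reduce(`+`, lapply(1:8, pmat))) / 8
  com_vel <- (Reduce(`+`, lapply(1:8, vmat))) / 8
  com_speed <- sqrt(rowSums(com_vel^2))

  head_p <- pmat(1L)
  neck_p <- pmat(2L)
  ctr <- (com + head_p + neck_p) / 3
  bv <- .principal_axis3(com - ctr, head_p - ctr, neck_p - ctr,
                         v0 = head_p - neck_p)
  # orient toward the head
  flip <- rowSums(bv * (head_p - ctr)) < 0
  bv[flip, ] <- -bv[flip, ]

  h <- sqrt(bv[, 1]^2 + bv[, 2]^2)
  degen <- h < 1e-9
  if (any(degen)) {
    log <- c(log, sprintf("degenerate (vertical) body vector at %d samples",
                          sum(degen)))
    h[degen] <- NA_real_
  }
  azimuth <- .unwrap(atan2(bv[, 2], bv[, 1]))
  elevation <- atan2(bv[, 3], h)
  turn_speed <- .central_diff(azimuth, fs)
  rear_speed <- .central_diff(elevation, fs)

  # body-frame axes
  rc <- cbind(bv[, 1] / h, bv[, 2] / h, 0)            # rostrocaudal (horizontal)
  rl <- cbind(-rc[, 2], rc[, 1], 0)                   # right-left (z x rc)

  aspects <- matrix(NA_real_, nrow = 27L, ncol = n)
  aspects[1, ] <- com_speed
  aspects[2, ] <- turn_speed
  aspects[3, ] <- rear_speed
  for (b in 1:8) {
    rel <- vmat(b) - com_vel
    i0 <- 3L + (b - 1L) * 3L
    aspects[i0 + 1L, ] <- rowSums(rel * rc)
    aspects[i0 + 2L, ] <- rowSums(rel * rl)
    aspects[i0 + 3L, ] <- rel[, 3]
  }
  aspect_names <- c("com_speed", "turn_speed", "rear_speed",
                    paste(rep(beads$bead_labels, each = 3L),
                          rep(c("rostrocaudal", "right_left", "up_down"), 8L),
                          sep = "_"))
  rownames(aspects) <- aspect_names
  structure(list(sample_rate_hz = fs,
                 bead_speeds = pre$speeds,
                 mean_body_speed = colMeans(pre$speeds),
                 aspects = aspects,
                 aspect_names = aspect_names,
                 body_vector = bv,
                 log = log),
            class = "kinematics_series")
}

#' @export
print.kinematics_series <- function(x, ...) {
  cat(sprintf("<kinematics_series> %d samples @ %g Hz, 27 aspects\n",
              length(x$mean_body_speed), x$sample_rate_hz))
  invisible(x)
}

#' Export the 27 aspect series to CSV
#' @param k a `kinematics_series`.
#' @param path output path.
#' @export
export_aspects <- function(k, path) {
  n <- ncol(k$aspects)
  df <- data.frame(time_s = (seq_len(n) - 1L) / k$sample_rate_hz)
  for (i in 1:27) df[[sprintf("aspect_%02d", i)]] <- k$aspects[i, ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
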