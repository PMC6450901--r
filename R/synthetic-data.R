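#' @title Synthetic sessions with known coupling structure
#' @description Generates 30-minute sessions of spike trains plus 8-bead 3D
#'   trajectories in which both kinds of coupling are planted and known. Body
#'   movement alternates between exponential rest and movement bouts; the mean
#'   body speed follows a smoothed bout indicator. Each unit's firing
#'   intensity is
#'   \deqn{\lambda_i(t) = \max(0,\; r_i \,[1 + a_i L(t) + g\, b_i u(t - \ell_i)])}
#'   with a shared low-pass-filtered unit-variance latent `L(t)` driving
#'   population coupling through the gains `a_i`, and the standardized body
#'   speed `u(t)` driving body coupling through the gains `b_i` (scaled by the
#'   movement gain `g`). Spikes are drawn as an inhomogeneous Poisson process
#'   by thinning. Bead trajectories advance the center of mass at the bout
#'   speed along a heading that oscillates during movement (driving the
#'   turning aspect), with rigid anatomical bead offsets plus posture jitter.
#' @name synthetic-data
NULL

# anatomical bead offsets in the body frame (rostrocaudal, right-left, up-down), mm
.BEAD_OFFSETS <- matrix(c(
   80, 0, 15,    # head
   50, 0,  8,    # neck_base
   20, 0,  0,    # back_1
    0, 0,  0,    # back_2
  -20, 0,  0,    # back_3
  -40, 0,  0,    # back_4
  -60, 0, -3,    # hips
  -80, 0, -8),   # tail_base
  ncol = 3L, byrow = TRUE)

#' Parameters of the synthetic-session generator
#'
#' Defaults emulate the recorded sessions: 30 minutes, ~5-30 units with
#' lognormal firing rates of median 2 Hz (floored above the 0.5 Hz exclusion
#' threshold), rest bouts of mean 5 s alternating with movement bouts of mean
#' 3 s, movement speed around 50 mm/s, a shared latent with 300 ms timescale,
#' and a movement-locked rate modulation of 30% per unit body-coupling gain
#' and SD of body speed.
#'
#' @param n_units number of units (default 20).
#' @param duration_s session length in seconds (default 1800; >= 120).
#' @param rate_median_hz,rate_sdlog lognormal base-rate parameters.
#' @param rate_min_hz floor applied to base rates (default 0.6 Hz, above the
#'   0.5 Hz exclusion threshold).
#' @param a latent (population-coupling) gains, length `n_units` or `NULL` to
#'   draw uniform on `[0, 1]`; must be >= -1.
#' @param b movement (body-coupling) gains, length `n_units` or `NULL` to
#'   draw uniform on `[0, 1]`.
#' @param latent_timescale_s latent low-pass timescale (default 0.3 s).
#' @param latent_gain scale of the latent drive (default 1).
#' @param movement_gain rate modulation per unit `b` per SD of body speed
#'   (default 0.3).
#' @param rest_mean_s,move_mean_s exponential bout means (defaults 5 s, 3 s).
#' @param move_speed_mm_s movement-bout speed amplitude (default 50 mm/s).
#' @param rest_speed_sd_mm_s positive speed jitter at rest (default 2 mm/s).
#' @param turn_amplitude_rad_s heading angular-speed scale during movement
#'   (default 1 rad/s).
#' @param posture_jitter_mm per-bead position jitter SD (default 1 mm).
#' @param latency_s response latency applied to the movement drive
#'   (scalar or per-unit; default 0).
#' @param sample_rate_hz kinematic sampling rate (default 100).
#' @param seed RNG seed (default `NULL`: use the current stream).
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_units = 20L, duration_s = 1800,
                         rate_median_hz = 2, rate_sdlog = 0.6,
                         rate_min_hz = 0.6,
                         a = NULL, b = NULL,
                         latent_timescale_s = 0.3, latent_gain = 1,
                         movement_gain = 0.3,
                         rest_mean_s = 5, move_mean_s = 3,
                         move_speed_mm_s = 50, rest_speed_sd_mm_s = 2,
                         turn_amplitude_rad_s = 1, posture_jitter_mm = 1,
                         latency_s = 0, sample_rate_hz = 100, seed = NULL) {
  stopifnot(duration_s >= 120, n_units >= 1L, rate_median_hz > 0)
  if (!is.null(a) && any(a < -1)) stop("latent gains must be >= -1")
  structure(as.list(environment()), class = "synth_params")
}

# alternating exponential rest/move bouts as a 0/1 indicator series
.bout_indicator <- function(n, fs, rest_mean_s, move_mean_s) {
  state <- integer(0)
  moving <- FALSE
  while (length(state) < n) {
    len <- stats::rexp(1, 1 / if (moving) move_mean_s else rest_mean_s)
    state <- c(state, rep.int(as.integer(moving), max(1L, round(len * fs))))
    moving <- !moving
  }
  state[seq_len(n)]
}

# unit-variance low-pass-filtered Gaussian series
.smooth_noise <- function(n, fs, cutoff_hz) {
  z <- lowpass_zero_phase(stats::rnorm(n), cutoff_hz, fs)
  z / stats::sd(z)
}

# inhomogeneous Poisson spikes by thinning; lambda sampled at fs
.thin_poisson <- function(lambda, fs, duration_s) {
  lmax <- max(lambda)
  if (lmax <= 0) return(numeric(0))
  if (lmax > 1000) {
    warning("intensity clipped at 1000 Hz")
    lambda <- pmin(lambda, 1000)
    lmax <- 1000
  }
  n_cand <- stats::rpois(1L, lmax * duration_s)
  if (n_cand == 0L) return(numeric(0))
  cand <- stats::runif(n_cand, 0, duration_s)
  idx <- pmin(pmax(round(cand * fs) + 1L, 1L), length(lambda))
  keep <- stats::runif(n_cand) * lmax < lambda[idx]
  sort(cand[keep])
}

#' Generate one synthetic session
#'
#' @param p a [synth_params()].
#' @return list with `session` (a [session()]), `ground_truth` (data.frame
#'   `unit_id`, `a`, `b`, `aspect`, `latency_s`, `rate_hz`), `speed` (the
#'   generator's mean-speed series), `latent` (the shared latent series).
#' @export
generate_session <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  fs <- p$sample_rate_hz
  n <- round(p$duration_s * fs)

  ind <- .bout_indicator(n, fs, p$rest_mean_s, p$move_mean_s)
  base <- lowpass_zero_phase(as.numeric(ind), 1, fs)
  # within-bout speed fluctuates on a sub-second timescale (lognormal
  # envelope, CV ~ 0.5): movement is bursts of accelerations, not a plateau
  env <- exp(0.5 * .smooth_noise(n, fs, 1.5) - 0.125)
  jitter <- abs(.smooth_noise(n, fs, 2)) * p$rest_speed_sd_mm_s
  speed <- pmax(0, base * p$move_speed_mm_s * env + jitter)

  latent <- .smooth_noise(n, fs, 1 / (2 * pi * p$latent_timescale_s))
  u <- (speed - mean(speed)) / stats::sd(speed)

  a <- p$a %||% stats::runif(p$n_units, 0, 1)
  b <- p$b %||% stats::runif(p$n_units, 0, 1)
  lat <- rep_len(p$latency_s, p$n_units)
  rates <- pmax(p$rate_min_hz,
                stats::rlnorm(p$n_units, log(p$rate_median_hz), p$rate_sdlog))

  spikes <- vector("list", p$n_units)
  for (i in seq_len(p$n_units)) {
    shift <- round(lat[i] * fs)
    u_i <- if (shift > 0) c(rep(u[1L], shift), u[seq_len(n - shift)]) else u
    lambda <- pmax(0, rates[i] * (1 + p$latent_gain * a[i] * latent +
                                    p$movement_gain * b[i] * u_i))
    spikes[[i]] <- .thin_poisson(lambda, fs, p$duration_s)
  }
  unit_ids <- sprintf("u%02d", seq_len(p$n_units))
  names(spikes) <- unit_ids
  # guard the right-open interval
  spikes <- lapply(spikes, function(t) t[t < p$duration_s])

  # heading oscillates during movement on a sub-second timescale,
  # driving the turning aspect
  turn_rate <- p$turn_amplitude_rad_s * .smooth_noise(n, fs, 0.75) * base
  theta <- cumsum(turn_rate) / fs
  step <- speed / fs
  com <- cbind(cumsum(step * cos(theta)), cumsum(step * sin(theta)), 30)
  pos <- array(0, dim = c(8L, n, 3L))
  for (bd in 1:8) {
    off <- .BEAD_OFFSETS[bd, ]
    pos[bd, , 1] <- com[, 1] + off[1] * cos(theta) - off[2] * sin(theta) +
      stats::rnorm(n, 0, p$posture_jitter_mm)
    pos[bd, , 2] <- com[, 2] + off[1] * sin(theta) + off[2] * cos(theta) +
      stats::rnorm(n, 0, p$posture_jitter_mm)
    pos[bd, , 3] <- com[, 3] + off[3] + stats::rnorm(n, 0, p$posture_jitter_mm)
  }

  sess <- session(
    session_id = sprintf("synth_%s", if (is.null(p$seed)) "x" else p$seed),
    spikes = spike_train_set(spikes, p$duration_s),
    beads = bead_trajectories(pos, BEAD_LABELS, fs))
  gt <- data.frame(unit_id = unit_ids, a = a, b = b, aspect = 1L,
                   latency_s = lat, rate_hz = rates)
  list(session = sess, ground_truth = gt, speed = speed, latent = latent)
}

#' Generate a multi-session population with a planted peaked relationship
#'
#' Latent gains span 0-1 evenly within each session; the movement gains
#' follow a Gaussian hump centred at `peak_location` (a fractional position
#' along the latent-gain range) plus noise, so the realized body coupling is
#' a peaked function of the realized population coupling. Session-level
#' multiplicative jitter on the base rates exercises median normalization.
#'
#' @param n_sessions number of sessions (default 5).
#' @param units_per_session units per session (default 40).
#' @param peak_location fractional position of the hump along the gain range
#'   (default 0.5).
#' @param hump_width Gaussian hump width on the gain scale (default 0.2).
#' @param noise_sd SD of the additive noise on the movement gains
#'   (default 0.1).
#' @param session_jitter_range multiplicative range of the per-session rate
#'   jitter (default `c(0.5, 2)`).
#' @param seed RNG seed.
#' @param ... further arguments passed to [synth_params()].
#' @return list with `sessions` (list of [generate_session()] outputs),
#'   `peak_location`, `ground_truth` (row-bound with session ids).
#' @export
generate_peaked_population <- function(n_sessions = 5L, units_per_session = 40L,
                                       peak_location = 0.5, hump_width = 0.2,
                                       noise_sd = 0.1,
                                       session_jitter_range = c(0.5, 2),
                                       seed = NULL, ...) {
  stopifnot(n_sessions >= 1L)
  if (!is.null(seed)) set.seed(seed)
  sessions <- vector("list", n_sessions)
  gt_all <- NULL
  for (s in seq_len(n_sessions)) {
    a <- seq(0, 1, length.out = units_per_session)
    b <- pmax(0, exp(-(a - peak_location)^2 / (2 * hump_width^2)) +
                stats::rnorm(units_per_session, 0, noise_sd))
    jit <- stats::runif(1, session_jitter_range[1], session_jitter_range[2])
    p <- synth_params(n_units = units_per_session, a = a, b = b,
                      rate_median_hz = 2 * jit, seed = NULL, ...)
    sessions[[s]] <- generate_session(p)
    sessions[[s]]$session$session_id <- sprintf("peaked_%02d", s)
    gt <- sessions[[s]]$ground_truth
    gt$session_id <- sessions[[s]]$session$session_id
    gt_all <- rbind(gt_all, gt)
  }
  list(sessions = sessions, peak_location = peak_location,
       ground_truth = gt_all)
}

#' Write a ground-truth table as CSV
#' @param ground_truth data.frame from [generate_session()].
#' @param path output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.csv(ground_truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
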