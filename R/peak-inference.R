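#' @title Peakiness permutation test and per-session consistency
#' @description Statistics for a non-monotonic, peaked relationship between a
#'   per-unit body-coupling value `y` and population coupling `x`. The
#'   candidate peak location `x*` is scanned over the observed `x` values
#'   (excluding the 10 smallest and 10 largest); for each candidate the
#'   Spearman correlation `rho_left` over points with `x < x*` and `rho_right`
#'   over points with `x > x*` are computed; a peak requires
#'   `rho_left > 0` and `rho_right < 0`, and the peakiness is
#'   `P = min(rho_left, -rho_right)` at the maximizing candidate (`P = 1` for
#'   a noiseless perfect peak, `P = 0` when no candidate qualifies). The
#'   permutation test shuffles `x` against `y`. A per-session quadratic-fit
#'   test judges whether each recording is consistent with the pooled peak.
#' @name peak-inference
NULL

.spearman <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

# lean scan: returns only the maximal P (0 when no valid candidate)
.peakiness_stat <- function(x, y, n_extreme = 10L) {
  n <- length(x)
  xs <- sort(x)
  cand <- unique(xs[(n_extreme + 1L):(n - n_extreme)])
  best <- 0
  for (v in cand) {
    li <- x < v
    ri <- x > v
    rl <- .spearman(x[li], y[li])
    if (is.na(rl) || rl <= 0) next
    rr <- .spearman(x[ri], y[ri])
    if (is.na(rr) || rr >= 0) next
    p <- min(rl, -rr)
    if (p > best) best <- p
  }
  best
}

#' Peakiness statistic and peak location
#'
#' @param x per-unit population coupling (finite).
#' @param y per-unit body coupling.
#' @param n_extreme number of extreme points excluded at each end of the
#'   candidate scan (default 10).
#' @return list with `x_star` (`NA` if no valid candidate), `P`, `rho_left`,
#'   `rho_right` at the peak, and `candidates` (data.frame of the valid
#'   candidates with their correlations).
#' @export
peakiness <- function(x, y, n_extreme = 10L) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 2L * n_extreme + 1L) {
    stop("need more than ", 2L * n_extreme, " points for the candidate scan")
  }
  xs <- sort(x)
  cand <- unique(xs[(n_extreme + 1L):(n - n_extreme)])
  rows <- lapply(cand, function(v) {
    li <- x < v
    ri <- x > v
    rl <- .spearman(x[li], y[li])
    rr <- .spearman(x[ri], y[ri])
    if (is.na(rl) || is.na(rr) || rl <= 0 || rr >= 0) return(NULL)
    data.frame(x_candidate = v, rho_left = rl, rho_right = rr,
               P = min(rl, -rr))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L) {
    return(list(x_star = NA_real_, P = 0, rho_left = NA_real_,
                rho_right = NA_real_,
                candidates = data.frame(x_candidate = numeric(0),
                                        rho_left = numeric(0),
                                        rho_right = numeric(0),
                                        P = numeric(0))))
  }
  best <- which.max(tab$P)
  list(x_star = tab$x_candidate[best], P = tab$P[best],
       rho_left = tab$rho_left[best], rho_right = tab$rho_right[best],
       candidates = tab)
}

#' Permutation test for a peaked relationship
#'
#' Shuffles `x` against the fixed `y` `n_shuffles` times, recomputing the
#' peakiness for each shuffle (`P = 0` when a shuffle has no valid candidate).
#' The p-value uses the add-one estimator
#' `(1 + #\{P_shuffle >= P_obs\}) / (1 + n_shuffles)`; ties count against
#' significance, which keeps the p-values super-uniform under the null even
#' though the peakiness has an atom at zero.
#'
#' @inheritParams peakiness
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `peak_test`: the [peakiness()] fields plus
#'   `p_value`, `n_shuffles`, `shuffle_P`.
#' @export
peak_permutation_test <- function(x, y, n_shuffles = 1000L, seed = NULL,
                                  n_extreme = 10L) {
  if (!is.null(seed)) set.seed(seed)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  obs <- peakiness(x, y, n_extreme)
  shuffle_P <- vapply(seq_len(n_shuffles), function(s) {
    .peakiness_stat(sample(x), y, n_extreme)
  }, numeric(1L))
  obs$p_value <- (1 + sum(shuffle_P >= obs$P)) / (1 + n_shuffles)
  obs$n_shuffles <- n_shuffles
  obs$shuffle_P <- shuffle_P
  class(obs) <- "peak_test"
  obs
}

#' @export
print.peak_test <- function(x, ...) {
  cat(sprintf("<peak_test> P = %.3f at x* = %s; p = %.4g (%d shuffles)\n",
              x$P, format(x$x_star, digits = 3), x$p_value, x$n_shuffles))
  invisible(x)
}

#' Export a peak test result as JSON
#' @param pt a `peak_test`.
#' @param path output path.
#' @param seed seed used (recorded in the report).
#' @export
export_peak_test <- function(pt, path, seed = NA) {
  jsonlite::write_json(list(x_star = pt$x_star, P = pt$P,
                            p_value = pt$p_value, n_shuffles = pt$n_shuffles,
                            seed = seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Quadratic-fit consistency of one session with the pooled peak
#'
#' A least-squares second-order polynomial is fit to the session's `(x, y)`
#' points. The session is consistent if either (criterion "curvature+location")
#' the quadratic coefficient is negative and the fit maximum lies within 10%
#' of the pooled `x` range from the pooled peak, or (criterion "slope-left" /
#' "slope-right") more than half of the session's `x` span lies on one side of
#' the pooled peak and the fit's mean slope over that side of the fitted range
#' points toward the peak (positive on the left, negative on the right).
#'
#' @param x,y the session's per-unit values.
#' @param pooled_x_star pooled peak location from [peakiness()].
#' @param pooled_x_range pooled range of `x` (scalar, `max - min`).
#' @param location_tol fraction of the pooled range allowed between the fit
#'   maximum and the pooled peak (default 0.10).
#' @param min_units minimum points to attempt the fit (default 5).
#' @return object of class `session_fit`: `coefficients` (a2, a1, a0),
#'   `fit_max_x`, `consistent`, `criterion` (one of "curvature+location",
#'   "slope-left", "slope-right", "none", "skipped").
#' @export
session_consistency <- function(x, y, pooled_x_star, pooled_x_range,
                                location_tol = 0.10, min_units = 5L) {
  out <- function(co, fmx, consistent, criterion) {
    structure(list(coefficients = co, fit_max_x = fmx,
                   consistent = consistent, criterion = criterion),
              class = "session_fit")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_units) {
    return(out(c(a2 = NA, a1 = NA, a0 = NA), NA_real_, NA, "skipped"))
  }
  fit <- stats::lm(y ~ x + I(x^2))
  co <- stats::coef(fit)
  a0 <- unname(co[1L]); a1 <- unname(co[2L]); a2 <- unname(co[3L])
  if (anyNA(c(a0, a1, a2))) {
    return(out(c(a2 = a2, a1 = a1, a0 = a0), NA_real_, FALSE, "none"))
  }
  fit_max_x <- if (a2 < 0) -a1 / (2 * a2) else NA_real_
  if (!is.na(pooled_x_star) && a2 < 0 &&
      abs(fit_max_x - pooled_x_star) <= location_tol * pooled_x_range) {
    return(out(c(a2 = a2, a1 = a1, a0 = a0), fit_max_x, TRUE,
               "curvature+location"))
  }
  lo <- min(x); hi <- max(x)
  if (is.na(pooled_x_star) || hi <= lo) {
    return(out(c(a2 = a2, a1 = a1, a0 = a0), fit_max_x, FALSE, "none"))
  }
  frac_left <- min(max((pooled_x_star - lo) / (hi - lo), 0), 1)
  fval <- function(v) a0 + a1 * v + a2 * v^2
  if (frac_left > 0.5) {
    b <- min(hi, pooled_x_star)
    slope <- (fval(b) - fval(lo)) / (b - lo)
    return(out(c(a2 = a2, a1 = a1, a0 = a0), fit_max_x, slope > 0,
               if (slope > 0) "slope-left" else "none"))
  }
  if (frac_left < 0.5) {
    a <- max(lo, pooled_x_star)
    slope <- (fval(hi) - fval(a)) / (hi - a)
    return(out(c(a2 = a2, a1 = a1, a0 = a0), fit_max_x, slope < 0,
               if (slope < 0) "slope-right" else "none"))
  }
  out(c(a2 = a2, a1 = a1, a0 = a0), fit_max_x, FALSE, "none")
}

#' Count of consistent sessions with a randomization p-value
#'
#' Counts the sessions whose quadratic fit is consistent with the pooled peak,
#' then repeats the whole procedure (pooled peak location and every session
#' fit) on datasets where the body-coupling values are shuffled across all
#' units and sessions, keeping the population-coupling values in place.
#'
#' @param sessions list; each element a list or data.frame with elements/
#'   columns `x` and `y`.
#' @param n_randomizations number of shuffled datasets (default 1000).
#' @param seed optional RNG seed.
#' @param min_units sessions with fewer points are skipped (default 5).
#' @param n_extreme passed to the peakiness scan.
#' @return list with `count`, `n_sessions`, `p_value`, `pooled`
#'   ([peakiness()] result), `per_session` (list of `session_fit`),
#'   `null_counts`.
#' @export
consistency_count_test <- function(sessions, n_randomizations = 1000L,
                                   seed = NULL, min_units = 5L,
                                   n_extreme = 10L) {
  if (!is.null(seed)) set.seed(seed)
  sessions <- lapply(sessions, function(s) {
    keep <- is.finite(s$x) & is.finite(s$y)
    list(x = s$x[keep], y = s$y[keep])
  })
  sessions <- Filter(function(s) length(s$x) >= min_units, sessions)
  if (length(sessions) < 2L) {
    stop("need at least 2 sessions passing the ", min_units, "-unit rule")
  }
  x_all <- unlist(lapply(sessions, `[[`, "x"))
  y_all <- unlist(lapply(sessions, `[[`, "y"))
  sizes <- vapply(sessions, function(s) length(s$x), integer(1L))
  grp <- rep(seq_along(sessions), sizes)
  count_consistent <- function(y_vec) {
    pk <- peakiness(x_all, y_vec, n_extreme)
    rng <- diff(range(x_all))
    fits <- lapply(seq_along(sessions), function(i) {
      session_consistency(x_all[grp == i], y_vec[grp == i],
                          pk$x_star, rng, min_units = min_units)
    })
    list(count = sum(vapply(fits, function(f) isTRUE(f$consistent),
                            logical(1L))),
         pooled = pk, fits = fits)
  }
  obs <- count_consistent(y_all)
  null_counts <- vapply(seq_len(n_randomizations), function(r) {
    count_consistent(sample(y_all))$count
  }, numeric(1L))
  list(count = obs$count, n_sessions = length(sessions),
       p_value = (1 + sum(null_counts >= obs$count)) / (1 + n_randomizations),
       pooled = obs$pooled, per_session = obs$fits,
       null_counts = null_counts)
}

#' Session-median normalization
#'
#' Within each session, divides `x` by the session median of `x` and `y` by
#' the session median of `y`, reducing session-to-session scale variability
#' before pooling. Sessions whose median magnitude is below `guard` are
#' excluded and logged.
#'
#' @param sessions list; each element with elements `x` and `y` (and
#'   optionally `session_id`).
#' @param guard smallest usable median magnitude (default 1e-9).
#' @return list with `table` (data.frame `session`, `x`, `y`) and `log`.
#' @export
median_normalize <- function(sessions, guard = 1e-9) {
  log <- character(0)
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    id <- s$session_id %||% as.character(i)
    mx <- stats::median(s$x, na.rm = TRUE)
    my <- stats::median(s$y, na.rm = TRUE)
    if (!is.finite(mx) || !is.finite(my) || abs(mx) < guard || abs(my) < guard) {
      log <<- c(log, sprintf("session %s excluded: median too close to zero", id))
      return(NULL)
    }
    data.frame(session = id, x = s$x / mx, y = s$y / my)
  })
  list(table = do.call(rbind, rows), log = log)
}

#' Moving median/quartile summary curve
#'
#' Sorts the points by `x` and slides a window of a fixed point count,
#' reporting the window's median `x` together with the median and quartiles
#' of `y` — the summary curve drawn through body-coupling-versus-population-
#' coupling scatters.
#'
#' @param x,y point coordinates.
#' @param window number of points per window (>= 5, <= length(x)).
#' @return data.frame with `x_center`, `y_median`, `y_q1`, `y_q3`.
#' @export
moving_quartile_summary <- function(x, y, window) {
  n <- length(x)
  stopifnot(length(y) == n, window >= 5L, window <= n)
  o <- order(x)
  x <- x[o]; y <- y[o]
  starts <- seq_len(n - window + 1L)
  out <- t(vapply(starts, function(i) {
    yy <- y[i:(i + window - 1L)]
    c(stats::median(x[i:(i + window - 1L)]),
      stats::quantile(yy, c(0.5, 0.25, 0.75), names = FALSE))
  }, numeric(4L)))
  data.frame(x_center = out[, 1L], y_median = out[, 2L],
             y_q1 = out[, 3L], y_q3 = out[, 4L])
}

#' Export a summary curve as CSV
#' @param curve result of [moving_quartile_summary()].
#' @param path output path.
#' @export
export_summary_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
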