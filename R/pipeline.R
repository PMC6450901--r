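#' @title End-to-end session and pooled analyses
#' @description Orchestrates the full chain for one session (exclusions ->
#'   kinematics -> binned counts -> population coupling with rest/motion and
#'   half-session splits -> BC_M / BC_S / BC_D with surrogate significance)
#'   and for a pooled collection of sessions (pooled peak tests, the
#'   median-normalized variant, the per-session consistency count and the
#'   moving-quartile summary curves). Every random step is driven by the
#'   seed recorded in the configuration.
#' @name pipeline
NULL

#' Analysis run configuration
#'
#' @param bin_width_s spike-count bin width (default 0.25 s).
#' @param n_surrogates_sig surrogate count for BC_M / BC_S significance
#'   (default 1000).
#' @param n_surrogates_z surrogate count for BC_D z-scoring (default 100).
#' @param n_shuffles shuffle count for the peak permutation test
#'   (default 1000).
#' @param min_rate_hz unit exclusion threshold (default 0.5 Hz).
#' @param min_units session exclusion threshold (default 5).
#' @param seed top-level RNG seed (default 1).
#' @param reduced reduced-cost mode: 100 significance surrogates and 200
#'   shuffles (default `FALSE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(bin_width_s = 0.25, n_surrogates_sig = 1000L,
                       n_surrogates_z = 100L, n_shuffles = 1000L,
                       min_rate_hz = 0.5, min_units = 5L, seed = 1L,
                       reduced = FALSE) {
  if (reduced) {
    n_surrogates_sig <- 100L
    n_shuffles <- 200L
  }
  stopifnot(bin_width_s > 0, n_surrogates_sig >= 1L, n_surrogates_z >= 1L,
            n_shuffles >= 1L)
  structure(list(bin_width_s = bin_width_s,
                 n_surrogates_sig = as.integer(n_surrogates_sig),
                 n_surrogates_z = as.integer(n_surrogates_z),
                 n_shuffles = as.integer(n_shuffles),
                 min_rate_hz = min_rate_hz, min_units = as.integer(min_units),
                 seed = as.integer(seed), reduced = reduced),
            class = "run_config")
}

#' Analyze one session end to end
#'
#' @param sess a [session()] with beads present.
#' @param config a [run_config()].
#' @param compute_bcd compute BC_D for every unit (default `TRUE`; the most
#'   expensive stage).
#' @return list with `status` ("ok" or "excluded"), `table` (the per-unit
#'   coupling table), `c_pop`, `rest_motion`, `halves`, `events`, `kin`,
#'   `log`.
#' @export
analyze_session <- function(sess, config = run_config(), compute_bcd = TRUE) {
  set.seed(config$seed)
  excl <- apply_exclusions(sess, config$min_rate_hz, config$min_units)
  log <- excl$log
  if (excl$excluded) {
    return(list(status = "excluded", table = NULL, log = log))
  }
  sess <- excl$session
  if (is.null(sess$beads)) stop("session has no bead trajectories")
  kin <- compute_aspects(sess$beads)
  speed <- kin$mean_body_speed
  n_samples <- length(speed)
  fs <- kin$sample_rate_hz
  log <- c(log, kin$log)

  b <- bin_spikes(sess$spikes, config$bin_width_s)
  cp <- population_coupling(b)
  rm_cp <- rest_motion_coupling(b, speed, fs)
  hv <- half_session_coupling(b)
  log <- c(log, rm_cp$log, hv$log)

  events <- detect_events(speed, fs)
  log <- c(log, events$log)

  n_units <- length(sess$spikes$unit_ids)
  rows <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    times <- sess$spikes$spike_times[[i]]
    m <- body_coupling_mtasr(times, events, n_samples, fs,
                             n_surrogates = config$n_surrogates_sig)
    s <- body_coupling_stabs(times, speed, fs,
                             n_surrogates = config$n_surrogates_sig)
    d <- if (compute_bcd) {
      bcd(times, kin, n_surrogates = config$n_surrogates_z)
    } else {
      list(bc_d = NA_real_, best_aspect_index = NA_integer_,
           log = character(0))
    }
    log <- c(log, d$log)
    rows[[i]] <- data.frame(
      session_id = sess$session_id,
      unit_id = sess$spikes$unit_ids[i],
      rate_hz = length(times) / sess$spikes$duration_s,
      c_pop = unname(cp$c_pop[i]),
      bc_m = m$bc_m, bc_s = s$bc_s, bc_d = d$bc_d,
      bc_m_significant = m$significant,
      bc_s_significant = s$significant,
      best_aspect_index = d$best_aspect_index)
  }
  list(status = "ok", table = do.call(rbind, rows), c_pop = cp,
       rest_motion = rm_cp, halves = hv, events = events, kin = kin,
       log = log)
}

#' Pooled analysis across sessions
#'
#' Pools the per-unit coupling tables, runs the peak permutation test for
#' each requested body-coupling measure against population coupling, repeats
#' it after session-median normalization, runs the per-session consistency
#' count test, and computes moving-quartile summary curves.
#'
#' @param tables list of per-session coupling tables (from
#'   [analyze_session()], `$table`).
#' @param config a [run_config()].
#' @param measures which body-coupling columns to analyze.
#' @param summary_window window (points) for the summary curves; `NULL`
#'   chooses a tenth of the pooled points (at least 5).
#' @return list keyed by measure: each with `peak` (a `peak_test`),
#'   `normalized_peak`, `consistency` (or `NULL` when fewer than two
#'   sessions), `summary_curve`; plus `pooled` (the pooled table) and `log`.
#' @export
analyze_pooled <- function(tables, config = run_config(),
                           measures = c("bc_m", "bc_s", "bc_d"),
                           summary_window = NULL) {
  pooled <- do.call(rbind, tables)
  log <- character(0)
  out <- list()
  for (m in measures) {
    keep <- is.finite(pooled$c_pop) & is.finite(pooled[[m]])
    x <- pooled$c_pop[keep]
    y <- pooled[[m]][keep]
    sid <- pooled$session_id[keep]
    pk <- peak_permutation_test(x, y, config$n_shuffles, seed = config$seed)
    sessions <- lapply(split(seq_along(x), sid),
                       function(i) list(x = x[i], y = y[i]))
    norm <- median_normalize(sessions)
    log <- c(log, norm$log)
    npk <- if (!is.null(norm$table) && nrow(norm$table) > 20L) {
      peak_permutation_test(norm$table$x, norm$table$y, config$n_shuffles,
                            seed = config$seed + 1L)
    } else NULL
    cons <- if (length(sessions) >= 2L) {
      tryCatch(consistency_count_test(sessions,
                                      n_randomizations = config$n_shuffles,
                                      seed = config$seed + 2L,
                                      min_units = config$min_units),
               error = function(e) {
                 log <<- c(log, paste("consistency test:", conditionMessage(e)))
                 NULL
               })
    } else NULL
    w <- summary_window %||% max(5L, length(x) %/% 10L)
    curve <- if (length(x) >= w) moving_quartile_summary(x, y, w) else NULL
    out[[m]] <- list(peak = pk, normalized_peak = npk, consistency = cons,
                     summary_curve = curve)
  }
  out$pooled <- pooled
  out$log <- log
  out
}

#' Write a run manifest (configuration and seed) as JSON
#' @param config a [run_config()].
#' @param path output path.
#' @param extra optional named list appended to the manifest.
#' @export
write_run_manifest <- function(config, path, extra = list()) {
  jsonlite::write_json(c(unclass(config), extra,
                         list(package_version =
                                as.character(utils::packageVersion("popcoupling")))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
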