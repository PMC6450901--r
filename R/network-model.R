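#' @title Binary probabilistic network model with adaptation
#' @description A network of `N = 1000` binary neurons (80% excitatory, 20%
#'   inhibitory). At each time step neuron `i` spikes with probability
#'   \deqn{p_i(t) = \sigma\big( [\eta + \sum_j W_{ij} s_j(t-1)] \, r_i(t) \big)}
#'   where \eqn{\sigma} clips to `[0, 1]`, \eqn{\eta} is the constant external
#'   input, and the activity-dependent factor
#'   \deqn{r_i(t) = (1 + \chi + \alpha \sum_{\tau=t-T_r}^{t-1} s_i(\tau))^{-1}}
#'   reduces the firing probability after recent spiking; \eqn{\chi} offsets
#'   the local inhibition (positive = enhanced). The connectivity `W` carries
#'   lognormal weights (variate mean 0.5, variance 1), 20% negated columns,
#'   lognormal in-degrees (mean 20, variance 500) and is scaled so its
#'   spectral radius is exactly 1.
#' @name network-model
NULL

#' Model parameter set
#'
#' @param N number of neurons (default 1000).
#' @param frac_inhibitory fraction of inhibitory columns (default 0.2).
#' @param eta external input (dimensionless probability increment,
#'   default 8e-4).
#' @param chi local-inhibition offset (default 0; must keep `1 + chi > 0`).
#' @param alpha adaptation magnitude (default 0.1).
#' @param T_r adaptation window in steps (default 100).
#' @param n_steps simulated steps (default 50000).
#' @param weight_mean,weight_var mean and variance of the lognormal weight
#'   variate (defaults 0.5 and 1).
#' @param indegree_mean,indegree_var mean and variance of the lognormal
#'   in-degree distribution (defaults 20 and 500).
#' @param model_bin spike-count bin width in steps (default 50).
#' @param subset_size,n_subsets population-coupling groups: `n_subsets`
#'   disjoint subsets of `subset_size` neurons (defaults 20 and 50).
#' @return object of class `model_params`.
#' @export
model_params <- function(N = 1000L, frac_inhibitory = 0.2, eta = 8e-4,
                         chi = 0, alpha = 0.1, T_r = 100L, n_steps = 50000L,
                         weight_mean = 0.5, weight_var = 1,
                         indegree_mean = 20, indegree_var = 500,
                         model_bin = 50L, subset_size = 20L, n_subsets = 50L) {
  stopifnot(frac_inhibitory > 0, frac_inhibitory < 1, T_r >= 1L,
            subset_size * n_subsets <= N, alpha >= 0)
  if (1 + chi <= 0) stop("chi = ", chi, " makes 1 + chi non-positive")
  structure(list(N = as.integer(N), frac_inhibitory = frac_inhibitory,
                 eta = eta, chi = chi, alpha = alpha, T_r = as.integer(T_r),
                 n_steps = as.integer(n_steps), weight_mean = weight_mean,
                 weight_var = weight_var, indegree_mean = indegree_mean,
                 indegree_var = indegree_var, model_bin = as.integer(model_bin),
                 subset_size = as.integer(subset_size),
                 n_subsets = as.integer(n_subsets)),
            class = "model_params")
}

# lognormal underlying-normal parameters from variate mean m and variance v
.lnorm_param <- function(m, v) {
  s2 <- log(1 + v / m^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# spectral radius: power iteration on the sparse matrix, dense fallback
.spectral_radius <- function(W, tol = 1e-10, max_iter = 5000L) {
  N <- nrow(W)
  x <- rep(1 / sqrt(N), N)
  lambda <- 0
  for (it in seq_len(max_iter)) {
    y <- as.numeric(W %*% x)
    ny <- sqrt(sum(y^2))
    if (ny < 1e-300) return(0)
    x_new <- y / ny
    lambda_new <- sum(x_new * as.numeric(W %*% x_new))
    if (it > 5L && abs(lambda_new - lambda) < tol * max(abs(lambda_new), 1)) {
      resid <- sqrt(sum((as.numeric(W %*% x_new) - lambda_new * x_new)^2))
      if (resid < 1e-6 * max(abs(lambda_new), 1)) return(abs(lambda_new))
    }
    lambda <- lambda_new
    x <- x_new
  }
  # dominant eigenvalue complex or gap too small: dense fallback
  max(Mod(eigen(as.matrix(W), only.values = TRUE)$values))
}

#' Construct the signed connectivity matrix
#'
#' Four steps: (1) draw an `N x N` lognormal matrix with variate mean
#' `weight_mean` and variance `weight_var` (underlying-normal parameters by
#' moment matching); (2) negate a uniformly random `frac_inhibitory` of the
#' columns; (3) prune each row to a lognormally distributed in-degree
#' (rounded, clipped to `[1, N-1]`, retained inputs chosen uniformly at
#' random, no self-connection); (4) divide the whole matrix by its spectral
#' radius so the largest eigenvalue modulus is 1.
#'
#' @param p a [model_params()].
#' @param seed optional RNG seed.
#' @return object of class `weight_matrix`: `W` (sparse `dgCMatrix`),
#'   `is_inhibitory` (per-column flag), `indegree`, `scale` (the spectral
#'   radius divided out), `raw_weight_mean` (sample mean of the step-one
#'   draws).
#' @export
build_weight_matrix <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- p$N
  wp <- .lnorm_param(p$weight_mean, p$weight_var)
  M <- matrix(stats::rlnorm(N * N, wp["meanlog"], wp["sdlog"]), N, N)
  raw_mean <- mean(M)
  n_inh <- round(p$frac_inhibitory * N)
  inh <- sample.int(N, n_inh)
  M[, inh] <- -M[, inh]
  kp <- .lnorm_param(p$indegree_mean, p$indegree_var)
  k <- pmin(pmax(round(stats::rlnorm(N, kp["meanlog"], kp["sdlog"])), 1L),
            N - 1L)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(N)) {
    keep <- sample.int(N - 1L, k[i])
    keep <- ifelse(keep >= i, keep + 1L, keep)   # skip the diagonal
    rows <- c(rows, rep.int(i, k[i]))
    cols <- c(cols, keep)
    vals <- c(vals, M[i, keep])
  }
  W <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  radius <- .spectral_radius(W)
  if (!is.finite(radius) || radius <= 0) stop("spectral radius not positive")
  W <- W / radius
  is_inh <- logical(N); is_inh[inh] <- TRUE
  structure(list(W = W, is_inhibitory = is_inh, indegree = as.integer(k),
                 scale = radius, raw_weight_mean = raw_mean),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d neurons, %.1f mean in-degree, %d inhibitory columns\n",
              nrow(x$W), mean(x$indegree), sum(x$is_inhibitory)))
  invisible(x)
}

#' Simulate the binary network
#'
#' Synchronous update from an all-silent initial state; the adaptation sum
#' runs over the available history while `t < T_r`.
#'
#' @param w a [build_weight_matrix()] result, or `NULL` for an unconnected
#'   network (`W = 0`).
#' @param p a [model_params()].
#' @param seed optional RNG seed.
#' @param record_raster keep the full binary raster (default `FALSE`; the
#'   binned counts are always kept).
#' @return object of class `sim_result`: `counts` (neurons x bins),
#'   `rates` (spikes/step), `n_steps`, `model_bin`, optionally `raster`.
#' @export
simulate_network <- function(w, p, seed = NULL, record_raster = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  N <- p$N
  if (1 + p$chi <= 0) stop("chi = ", p$chi, " makes the adaptation denominator non-positive")
  W <- if (is.null(w)) NULL else w$W
  n_bins <- p$n_steps %/% p$model_bin
  counts <- matrix(0L, N, n_bins)
  total <- numeric(N)
  s <- numeric(N)
  histbuf <- matrix(0, N, p$T_r)
  A <- numeric(N)
  raster <- if (record_raster) matrix(0L, N, p$n_steps) else NULL
  for (t in seq_len(p$n_steps)) {
    r <- 1 / (1 + p$chi + p$alpha * A)
    input <- if (is.null(W)) p$eta else p$eta + as.numeric(W %*% s)
    prob <- pmin(pmax(input * r, 0), 1)
    s <- as.numeric(stats::runif(N) < prob)
    bin <- (t - 1L) %/% p$model_bin + 1L
    if (bin <= n_bins) counts[, bin] <- counts[, bin] + s
    total <- total + s
    slot <- (t - 1L) %% p$T_r + 1L
    A <- A - histbuf[, slot] + s
    histbuf[, slot] <- s
    if (record_raster) raster[, t] <- s
  }
  structure(list(counts = counts, rates = total / p$n_steps,
                 n_steps = p$n_steps, model_bin = p$model_bin,
                 raster = raster),
            class = "sim_result")
}

#' Population coupling of model neurons within small subsets
#'
#' Spike counts are binned at `model_bin` steps; the neurons are partitioned
#' (seeded, uniformly at random) into `n_subsets` disjoint subsets of
#' `subset_size`, mimicking the small recorded populations, and each neuron's
#' population coupling is computed within its subset. Neurons with zero
#' spikes get `NA` (logged).
#'
#' @param sim a [simulate_network()] result.
#' @param p a [model_params()].
#' @param seed optional RNG seed for the partition.
#' @return list with `c_pop` (length `N`), `groups` (list of index vectors),
#'   `log`.
#' @export
model_population_coupling <- function(sim, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(sim$counts)
  perm <- sample.int(N)
  used <- p$subset_size * p$n_subsets
  groups <- split(perm[seq_len(used)],
                  rep(seq_len(p$n_subsets), each = p$subset_size))
  c_pop <- rep(NA_real_, N)
  log <- character(0)
  for (g in groups) {
    vals <- .cpop_core(sim$counts[g, , drop = FALSE])
    c_pop[g] <- vals
    if (anyNA(vals)) {
      log <- c(log, sprintf("neuron %d: zero spikes, C_pop undefined",
                            g[is.na(vals)]))
    }
  }
  list(c_pop = c_pop, groups = groups, log = log)
}

#' Named parameter grids for the input/inhibition sweeps
#'
#' `"fig3c"`: external input fixed at `eta = 8e-4`, local inhibition
#' `chi in {0.2, 0.1, 0, -0.1, -0.2}`. `"fig3d"`: `chi = 0`,
#' `eta in {2, 4, 8, 16, 32} x 1e-4`. `"fig3e"`: the three combined cases
#' `(eta, chi) = (4e-4, 0.1), (2e-3, 0), (5e-3, -0.1)`.
#'
#' @param name preset name.
#' @return data.frame with columns `eta`, `chi`.
#' @export
model_preset_grid <- function(name = c("fig3c", "fig3d", "fig3e")) {
  name <- match.arg(name)
  switch(name,
         fig3c = data.frame(eta = 8e-4, chi = c(0.2, 0.1, 0, -0.1, -0.2)),
         fig3d = data.frame(eta = c(2e-4, 4e-4, 8e-4, 1.6e-3, 3.2e-3), chi = 0),
         fig3e = data.frame(eta = c(4e-4, 2e-3, 5e-3), chi = c(0.1, 0, -0.1)))
}

#' Sweep the model over an (eta, chi) grid
#'
#' Each seed builds one connectivity realization and simulates every grid
#' point with it; summaries (mean and variance of the defined population-
#' coupling values, mean firing rate) are averaged over seeds.
#'
#' @param grid data.frame with columns `eta`, `chi` (see
#'   [model_preset_grid()]).
#' @param p a [model_params()] (its `eta`/`chi` are overridden per point).
#' @param seeds integer vector of seeds (default `1:3`).
#' @return data.frame with `eta`, `chi`, `mean_c_pop`, `var_c_pop`,
#'   `mean_rate`, `n_seeds`.
#' @export
sweep_model <- function(grid, p, seeds = 1:3) {
  acc <- array(0, dim = c(nrow(grid), 3L))
  for (s in seeds) {
    set.seed(s)
    w <- build_weight_matrix(p)
    for (i in seq_len(nrow(grid))) {
      pi <- p
      pi$eta <- grid$eta[i]
      pi$chi <- grid$chi[i]
      sim <- simulate_network(w, pi)
      mpc <- model_population_coupling(sim, pi)
      acc[i, 1L] <- acc[i, 1L] + mean(mpc$c_pop, na.rm = TRUE)
      acc[i, 2L] <- acc[i, 2L] + stats::var(mpc$c_pop, na.rm = TRUE)
      acc[i, 3L] <- acc[i, 3L] + mean(sim$rates)
    }
  }
  acc <- acc / length(seeds)
  data.frame(eta = grid$eta, chi = grid$chi, mean_c_pop = acc[, 1L],
             var_c_pop = acc[, 2L], mean_rate = acc[, 3L],
             n_seeds = length(seeds))
}

#' Run a named sweep preset
#' @param name preset name for [model_preset_grid()].
#' @param p a [model_params()].
#' @param seeds seeds for [sweep_model()].
#' @export
run_model_preset <- function(name, p = model_params(), seeds = 1:3) {
  sweep_model(model_preset_grid(name), p, seeds)
}

#' Export a raster as CSV (`neuron_id,step`)
#' @param sim a `sim_result` with `record_raster = TRUE`.
#' @param path output path.
#' @export
export_raster <- function(sim, path) {
  if (is.null(sim$raster)) stop("simulation was run without record_raster")
  idx <- which(sim$raster == 1L, arr.ind = TRUE)
  utils::write.csv(data.frame(neuron_id = idx[, 1L], step = idx[, 2L]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
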