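#' Simulate a stochastic Boolean trajectory
#'
#' Samples the synchronous stochastic dynamics: at each step every node's
#' next bit is drawn independently with its transition probability (tanh
#' response for non-zero effective input, basal flip `c` at zero input,
#' checkpoint excitation `gamma` in the resting state). Fully reproducible
#' from `seed` via R's RNG.
#'
#' @inheritParams build_transition_matrix
#' @param n_steps number of steps to simulate (>= 1).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param initial_state starting bit vector; defaults to the network's
#'   resting state (or all zeros if none is set).
#' @return an object of class `boolean_trajectory`: list with `states`
#'   (integer vector of 0-based state indices, length `n_steps + 1`),
#'   `n_nodes`, `params`, `seed`.
#' @export
simulate_trajectory <- function(net, params, n_steps, seed = NULL,
                                initial_state = NULL, max_nodes = 20L,
                                threshold_scaling = c("integer", "half")) {
  n <- n_nodes(net)
  if (n > max_nodes) stop("network too large for exact per-state tables")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (is.null(initial_state))
    initial_state <- if (!is.null(net$g0_state)) net$g0_state else integer(n)
  initial_state <- check_bits(initial_state, n)
  if (!is.null(seed)) set.seed(seed)
  p <- node_on_probabilities(net, params, threshold_scaling)
  states <- simulate_boolean_cpp(p, n, as.integer(n_steps),
                                 encode_state(initial_state))
  structure(list(states = states, n_nodes = n, params = params, seed = seed),
            class = "boolean_trajectory")
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat(sprintf("boolean_trajectory: %d steps on %d nodes\n",
              length(x$states) - 1L, x$n_nodes))
  invisible(x)
}

#' Per-gene observable series of a trajectory
#'
#' @param traj a `boolean_trajectory` (or integer vector of state indices).
#' @param n_nodes number of nodes (taken from the trajectory object when
#'   available).
#' @return integer matrix, one column per node, of the per-step bits.
#' @export
trajectory_bits <- function(traj, n_nodes = NULL) {
  if (inherits(traj, "boolean_trajectory")) {
    n_nodes <- traj$n_nodes
    traj <- traj$states
  }
  if (is.null(n_nodes)) stop("n_nodes required for a bare index vector")
  vapply(seq_len(n_nodes),
         function(i) bitwAnd(bitwShiftR(as.integer(traj), i - 1L), 1L),
         integer(length(traj)))
}

#' Simulate a generic finite Markov chain
#'
#' Utility sampler for explicit transition matrices (toy chains, oracle
#' tests): one state index per step.
#'
#' @param T row-stochastic transition matrix.
#' @param n_steps number of steps.
#' @param seed optional integer seed.
#' @param initial_state 0-based starting state index (default 0).
#' @return integer vector of 0-based state indices, length `n_steps + 1`.
#' @export
simulate_markov <- function(T, n_steps, seed = NULL, initial_state = 0L) {
  check_row_stochastic(T)
  if (!is.null(seed)) set.seed(seed)
  simulate_markov_cpp(T, as.integer(n_steps), as.integer(initial_state))
}

#' Autocorrelation of a time series
#'
#' Mean-subtracted, biased-normalized autocorrelation
#' \eqn{r_k = \frac{1}{n\,\sigma^2}\sum_{t=1}^{n-k}(x_t-\bar x)(x_{t+k}-\bar x)}
#' for lags `0..max_lag`; `r_0 = 1` for any non-constant series.
#'
#' @param series numeric vector.
#' @param max_lag maximum lag (< length of series).
#' @return numeric vector of length `max_lag + 1`.
#' @export
autocorrelation <- function(series, max_lag) {
  series <- as.numeric(series)
  n <- length(series)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  x <- series - mean(series)
  v <- sum(x^2) / n
  if (v == 0) stop("constant series: autocorrelation undefined (zero variance)")
  vapply(0:max_lag,
         function(k) sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / (n * v),
         numeric(1))
}

#' Power spectrum of a time series
#'
#' One-sided power spectrum on the frequency grid `k / n` cycles per step,
#' `k = 0..floor(n/2)`, computed as the discrete Fourier transform of the
#' (circular, biased) autocorrelation — equivalently the periodogram
#' \eqn{|X_k|^2/n^2} of the mean-removed series, folded one-sided. Without
#' a window the total one-sided power equals the biased variance of the
#' series (Parseval). The dominant frequency is the argmax over positive
#' frequencies (the zero-frequency bin is excluded).
#'
#' @param series numeric vector, length >= 64.
#' @param window `"none"` (default) or `"hann"`.
#' @return an object of class `spectrum_result`: list with `frequencies`,
#'   `power`, `dominant_frequency`, `dominant_power`.
#' @export
power_spectrum <- function(series, window = c("none", "hann")) {
  window <- match.arg(window)
  series <- as.numeric(series)
  n <- length(series)
  if (n < 64L) stop("series too short for a spectrum (need >= 64 points)")
  x <- series - mean(series)
  if (sum(x^2) == 0) stop("constant series: spectrum undefined (zero variance)")
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  X <- fft(x)
  pgram <- Mod(X)^2 / n^2
  half <- floor(n / 2)
  k <- 0:half
  power <- pgram[k + 1L]
  interior <- k > 0L & (2L * k < n)   # fold the conjugate half in
  power[interior] <- 2 * power[interior]
  freq <- k / n
  pos <- which(k > 0L)
  imax <- pos[which.max(power[pos])]
  structure(list(frequencies = freq, power = power,
                 dominant_frequency = freq[imax],
                 dominant_power = power[imax]),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum_result: %d bins, dominant frequency %.5g cycles/step\n",
              length(x$frequencies), x$dominant_frequency))
  invisible(x)
}

#' Spectrum of a Boolean trajectory observable
#'
#' Default observable `"mean-of-genes"` averages the per-gene power spectra
#' (the peak location of interest is shared across informative genes);
#' `"sum"` uses the total number of active genes per step; `"gene"` a
#' single named gene.
#'
#' @param traj a `boolean_trajectory`.
#' @param net the network (for gene names).
#' @param observable see Details.
#' @param gene gene name when `observable = "gene"`.
#' @inheritParams power_spectrum
#' @return a `spectrum_result`.
#' @export
trajectory_spectrum <- function(traj, net = NULL,
                                observable = c("mean-of-genes", "sum", "gene"),
                                gene = NULL, window = c("none", "hann")) {
  observable <- match.arg(observable)
  bits <- trajectory_bits(traj)
  if (observable == "sum")
    return(power_spectrum(rowSums(bits), window))
  if (observable == "gene") {
    if (is.null(net) || is.null(gene)) stop("gene observable needs net and gene")
    i <- match(gene, net$nodes)
    if (is.na(i)) stop("unknown gene: ", gene)
    return(power_spectrum(bits[, i], window))
  }
  specs <- lapply(seq_len(ncol(bits)), function(i) {
    x <- bits[, i]
    if (all(x == x[1L])) return(NULL)   # constant gene carries no signal
    power_spectrum(x, window)
  })
  specs <- specs[!vapply(specs, is.null, logical(1))]
  if (length(specs) == 0L) stop("all genes constant: spectrum undefined")
  power <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  freq <- specs[[1L]]$frequencies
  pos <- which(freq > 0)
  imax <- pos[which.max(power[pos])]
  structure(list(frequencies = freq, power = power,
                 dominant_frequency = freq[imax],
                 dominant_power = power[imax]),
            class = "spectrum_result")
}

#' Dominant frequency, flux and dissipation along a parameter grid
#'
#' For each value of the swept parameter: builds the exact chain, solves
#' the steady state, records the native-loop flux and the entropy
#' production rate, then simulates `n_replicates` trajectories and records
#' the mean and sd of the dominant spectral frequency. The table is the raw
#' material for the frequency–flux–dissipation correlations of a driven
#' oscillator.
#'
#' @inheritParams build_transition_matrix
#' @param param which parameter to sweep (`"gamma"`, `"mu"`, or `"c"`).
#' @param grid numeric vector of parameter values.
#' @param native_path [native_path()] used to identify the native loop.
#' @param n_steps trajectory length per replicate.
#' @param n_replicates trajectories per grid point.
#' @param seeds integer vector of seeds, one per (grid point, replicate);
#'   recycled along replicates with an offset per grid point.
#' @param observable passed to [trajectory_spectrum()].
#' @return data.frame with one row per grid value: `value`,
#'   `dominant_frequency`, `frequency_sd`, `native_flux`, `total_flux`,
#'   `ep_rate`.
#' @export
dominant_frequency_vs_parameter <- function(net, params, param = "gamma",
                                            grid, native_path,
                                            n_steps = 2^15, n_replicates = 2L,
                                            seeds = 1L,
                                            observable = "mean-of-genes",
                                            threshold_scaling = c("integer", "half")) {
  param <- match.arg(param, c("gamma", "mu", "c"))
  if (length(grid) == 0L) stop("empty parameter grid")
  threshold_scaling <- match.arg(threshold_scaling)
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    pl <- params
    pl[[param]] <- grid[g]
    pg <- model_parameters(pl$mu, pl$c, pl$gamma)
    T <- build_transition_matrix(net, pg, threshold_scaling = threshold_scaling)
    P <- solve_steady_state(T)
    loops <- extract_loops(flux_matrix(T, P))
    nat_flux <- 0
    if (length(loops$flux) > 0L) {
      hit <- which(vapply(loops$states, same_cycle, logical(1),
                          ref = native_path$indices))
      if (length(hit)) nat_flux <- sum(loops$flux[hit])
    }
    ep <- entropy_production_rate(T, P,
            log_T = log_transition_matrix(net, pg,
                      threshold_scaling = threshold_scaling))
    freqs <- vapply(seq_len(n_replicates), function(r) {
      sd_off <- (g - 1L) * n_replicates + r - 1L
      traj <- simulate_trajectory(net, pg, n_steps,
                                  seed = seeds[1L] + sd_off,
                                  threshold_scaling = threshold_scaling)
      trajectory_spectrum(traj, net, observable = observable)$dominant_frequency
    }, numeric(1))
    rows[[g]] <- data.frame(value = grid[g],
                            dominant_frequency = mean(freqs),
                            frequency_sd = if (n_replicates > 1L) sd(freqs) else NA_real_,
                            native_flux = nat_flux,
                            total_flux = loops$total_flux,
                            ep_rate = ep$finite_part)
  }
  do.call(rbind, rows)
}
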