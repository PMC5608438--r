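#' Model parameters of the stochastic Boolean kernel
#'
#' Three parameters control the node-level transition probabilities:
#' \describe{
#'   \item{`mu`}{response sharpness (inverse noise strength), `mu >= 0`.
#'     With a non-zero effective input \eqn{h}, a node switches on with
#'     probability \eqn{1/2 + \tanh(\mu h)/2}.}
#'   \item{`c`}{basal flip probability in `[0, 1]`: a node with zero
#'     effective input changes its current bit with probability `c`
#'     (background production / self-degradation).}
#'   \item{`gamma`}{cycling activation probability in `[0, 1]`: when the
#'     global state equals the resting G0 state, the checkpoint node turns
#'     on with probability `gamma` instead of `c` (the energy pump that
#'     launches a new cycle).}
#' }
#'
#' @param mu,c,gamma see Details.
#' @return an object of class `model_parameters`.
#' @export
model_parameters <- function(mu = 5, c = 0.001, gamma = 0.6) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0) stop("mu must be >= 0")
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 1)
    stop("c must be a probability in [0, 1]")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop("gamma must be a probability in [0, 1]")
  structure(list(mu = mu, c = c, gamma = gamma), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("model_parameters: mu = %g, c = %g, gamma = %g\n",
              x$mu, x$c, x$gamma))
  invisible(x)
}

#' Single-node transition probability
#'
#' The probability that a node's next bit is 1 given its effective input
#' \eqn{h} (total input minus threshold, possibly rescaled; see
#' [build_transition_matrix()]):
#' \itemize{
#'   \item \eqn{h \neq 0}: \eqn{1/2 + \tanh(\mu h)/2};
#'   \item \eqn{h = 0}, current bit 1: \eqn{1 - c};
#'   \item \eqn{h = 0}, current bit 0, ordinary node: \eqn{c};
#'   \item \eqn{h = 0}, current bit 0, checkpoint node while the global
#'     state is G0: \eqn{\gamma}.
#' }
#'
#' @param params a [model_parameters()] object.
#' @param I effective input (numeric scalar).
#' @param s_current current bit (0/1).
#' @param is_g0_checkpoint is this the checkpoint node evaluated in the
#'   resting G0 state?
#' @return probability that the next bit is 1.
#' @export
node_transition_prob <- function(params, I, s_current, is_g0_checkpoint = FALSE) {
  if (I != 0) return(0.5 + 0.5 * tanh(params$mu * I))
  if (s_current == 1) return(1 - params$c)
  if (is_g0_checkpoint) params$gamma else params$c
}

# effective inputs (with optional integer rescaling of half-integer
# thresholds) for every state; returns an N x n matrix
effective_input_table <- function(net, threshold_scaling = c("integer", "half")) {
  threshold_scaling <- match.arg(threshold_scaling)
  bits <- state_table(n_nodes(net))
  h <- bits %*% t(net$interactions)
  h <- sweep(h, 2L, net$thresholds)
  if (threshold_scaling == "integer") {
    frac <- which(net$thresholds %% 1 != 0)
    h[, frac] <- 2 * h[, frac]
  }
  h
}

# per-node log on/off probabilities for every from-state, computed in a
# saturation-safe form: 1/2 + tanh(mu*h)/2 = plogis(2*mu*h), whose log is
# -log1p(exp(-2*mu*h)) and stays finite down to ~1e-300 even where tanh
# rounds to 1 in double precision
node_log_probabilities <- function(net, params,
                                   threshold_scaling = c("integer", "half")) {
  h <- effective_input_table(net, threshold_scaling)
  bits <- state_table(n_nodes(net))
  x <- 2 * params$mu * h
  lon <- ifelse(x < -700, x, -log1p(exp(-x)))     # log plogis(x), overflow-safe
  loff <- ifelse(x > 700, -x, -log1p(exp(x)))     # log plogis(-x)
  z <- h == 0
  s1 <- z & bits == 1L
  s0 <- z & bits == 0L
  lon[s1] <- log1p(-params$c);  loff[s1] <- log(params$c)
  lon[s0] <- log(params$c);     loff[s0] <- log1p(-params$c)
  if (!is.null(net$g0_state)) {
    g0row <- encode_state(net$g0_state) + 1L
    cp <- net$checkpoint
    if (h[g0row, cp] == 0 && net$g0_state[cp] == 0L) {
      lon[g0row, cp] <- log(params$gamma)
      loff[g0row, cp] <- log1p(-params$gamma)
    }
  }
  list(lon = lon, loff = loff)
}

#' Log-transition matrix
#'
#' Element-wise natural log of the transition matrix, computed factor-wise
#' so that entries far below double-precision underflow (products of many
#' saturated tanh factors) keep their true magnitude. Needed by
#' [entropy_production_rate()], whose affinities are log ratios of flows
#' that can be as small as e^-1400 for sharp response (`mu >= 5`).
#'
#' @inheritParams build_transition_matrix
#' @return matrix of log probabilities (`-Inf` only where the model is
#'   genuinely zero, e.g. `c = 0`).
#' @export
log_transition_matrix <- function(net, params, max_nodes = 20L,
                                  threshold_scaling = c("integer", "half")) {
  n <- n_nodes(net)
  if (n > max_nodes) stop("network too large")
  lp <- node_log_probabilities(net, params, threshold_scaling)
  bits <- state_table(n)
  N <- 2L^n
  L <- matrix(0, N, N)
  for (i in seq_len(n)) {
    b <- bits[, i]
    L <- L + lp$lon[, i] %o% b + lp$loff[, i] %o% (1 - b)
  }
  L
}

# N x n matrix of per-node on-probabilities for every from-state,
# including the gamma rule at the G0 row
node_on_probabilities <- function(net, params,
                                  threshold_scaling = c("integer", "half")) {
  h <- effective_input_table(net, threshold_scaling)
  bits <- state_table(n_nodes(net))
  p <- 0.5 + 0.5 * tanh(params$mu * h)
  z <- h == 0
  p[z & bits == 1L] <- 1 - params$c
  p[z & bits == 0L] <- params$c
  if (!is.null(net$g0_state)) {
    g0row <- encode_state(net$g0_state) + 1L
    cp <- net$checkpoint
    if (h[g0row, cp] == 0 && net$g0_state[cp] == 0L)
      p[g0row, cp] <- params$gamma
  }
  p
}

#' Global state-to-state transition probability
#'
#' The one-step probability of jumping from `from` to `to` is the product of
#' the independent node transitions,
#' \eqn{T(S'|S) = \prod_i T(s_i'|S)}; summed over all \eqn{2^n} targets it
#' equals 1.
#'
#' @param net a `regulatory_network`.
#' @param params a [model_parameters()] object.
#' @param from,to bit vectors.
#' @param threshold_scaling see [build_transition_matrix()].
#' @return the transition probability.
#' @export
state_transition_prob <- function(net, params, from, to,
                                  threshold_scaling = c("integer", "half")) {
  n <- n_nodes(net)
  from <- check_bits(from, n); to <- check_bits(to, n)
  h <- as.vector(net$interactions %*% from) - net$thresholds
  if (match.arg(threshold_scaling) == "integer") {
    frac <- net$thresholds %% 1 != 0
    h[frac] <- 2 * h[frac]
  }
  is_g0 <- !is.null(net$g0_state) && all(from == net$g0_state)
  p1 <- vapply(seq_len(n), function(i)
    node_transition_prob(params, h[i], from[i],
                         is_g0_checkpoint = is_g0 && i == net$checkpoint),
    numeric(1))
  prod(ifelse(to == 1L, p1, 1 - p1))
}

#' Build the full state-space transition matrix
#'
#' Assembles the dense `2^n x 2^n` row-stochastic one-step kernel `T`,
#' with `T[i + 1, j + 1]` the probability of jumping from state index `i`
#' to state index `j` (canonical indexing, see [encode_state()]).
#'
#' `threshold_scaling` fixes the stochasticization of nodes carrying a
#' half-integer activation threshold, for which the effective input
#' \eqn{I - \theta} is never 0: `"integer"` (default) rescales it to the
#' integer lattice (\eqn{2(I-\theta)}, so the sharpness `mu` acts on the
#' same integer scale for every node), `"half"` uses \eqn{I - \theta}
#' as is. Both have the same deterministic limit; see the methods vignette
#' for how the default was selected.
#'
#' @inheritParams state_transition_prob
#' @param max_nodes size guard: refuse networks with more than this many
#'   nodes (the matrix has `4^n` entries).
#' @return a dense row-stochastic matrix.
#' @export
build_transition_matrix <- function(net, params, max_nodes = 20L,
                                    threshold_scaling = c("integer", "half")) {
  n <- n_nodes(net)
  if (n > max_nodes)
    stop(sprintf("network has %d nodes; state space 2^%d exceeds the cap (max_nodes = %d)",
                 n, n, max_nodes))
  p <- node_on_probabilities(net, params, threshold_scaling)
  bits <- state_table(n)
  N <- 2L^n
  T <- matrix(1, N, N)
  for (i in seq_len(n)) {
    b <- bits[, i]
    T <- T * (p[, i] %o% b + (1 - p[, i]) %o% (1 - b))
  }
  T
}

#' Evolve a probability vector under the master equation
#'
#' Applies the discrete-time master equation
#' \eqn{P_j(t+1) = \sum_i T_{ij} P_i(t)} for `n_steps` steps.
#'
#' @param T row-stochastic transition matrix.
#' @param P0 initial probability vector (normalized).
#' @param n_steps number of steps (>= 0).
#' @return the evolved probability vector.
#' @export
evolve_probability <- function(T, P0, n_steps) {
  check_probability(P0, nrow(T))
  P <- P0
  if (n_steps > 0) {
    Tt <- t(T)
    for (k in seq_len(n_steps)) P <- as.vector(Tt %*% P)
  }
  P
}

check_probability <- function(P, N = NULL, tol = 1e-10) {
  if (!is.null(N) && length(P) != N)
    stop("probability vector length does not match the matrix")
  if (any(P < -tol)) stop("probability vector has negative entries")
  if (abs(sum(P) - 1) > tol) stop("probability vector is not normalized")
  invisible(P)
}

check_row_stochastic <- function(T, tol = 1e-12) {
  if (!is.matrix(T) || nrow(T) != ncol(T)) stop("T must be a square matrix")
  if (any(T < -tol) || any(T > 1 + tol)) stop("T entries must lie in [0, 1]")
  if (max(abs(rowSums(T) - 1)) > max(tol, 1e-12) * nrow(T))
    stop("T rows must sum to 1")
  invisible(T)
}

# strong connectivity of the support graph (positive entries), by two BFS
is_irreducible <- function(T, eps = 0) {
  N <- nrow(T)
  reach <- function(M) {
    seen <- logical(N); seen[1L] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(M[frontier, , drop = FALSE] > eps) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  reach(T) && reach(t(T))
}

#' Solve for the stationary distribution
#'
#' Computes the steady state \eqn{P^{ss}} with \eqn{T' P^{ss} = P^{ss}} by a
#' direct dense solve of the stationarity system (one equation replaced by
#' the normalization), followed by positivity-preserving power-iteration
#' refinement. The refinement matters: stationary probabilities of strongly
#' suppressed states can lie far below the absolute accuracy of the linear
#' solve, and the landscape statistics take logs of them. Because the
#' refinement sums only nonnegative terms, it restores full *relative*
#' accuracy for arbitrarily small entries.
#'
#' @param T row-stochastic transition matrix.
#' @param tol target residual \eqn{\|T'P - P\|_\infty}.
#' @param max_iter refinement cap.
#' @return the stationary probability vector. If the chain is reducible
#'   (stationary distribution possibly non-unique) a warning reports it and
#'   the returned vector is the one selected by the solver.
#' @export
solve_steady_state <- function(T, tol = 1e-12, max_iter = 5000L) {
  check_row_stochastic(T)
  N <- nrow(T)
  if (!is_irreducible(T))
    warning("transition matrix is reducible: stationary distribution may not be unique")
  A <- t(T) - diag(N)
  A[N, ] <- 1
  P <- tryCatch(solve(A, c(rep(0, N - 1L), 1)),
                error = function(e) rep(1 / N, N))
  P <- pmax(P, 0)
  s <- sum(P)
  P <- if (s > 0) P / s else rep(1 / N, N)
  Tt <- t(T)
  iter <- 0L
  repeat {
    Pold <- P
    for (k in seq_len(50L)) P <- as.vector(Tt %*% P)
    P <- P / sum(P)
    iter <- iter + 50L
    res <- max(abs(as.vector(Tt %*% P) - P))
    # relative settling of the small entries (they enter the landscape logs)
    pos <- P > 0 & Pold > 0
    relchg <- if (any(pos)) max(abs(log(P[pos] / Pold[pos]))) else 0
    if ((res <= tol && relchg <= 1e-9) || iter >= max_iter) break
  }
  if (res > tol)
    warning(sprintf("steady state residual %.3g above tol %.3g after %d refinement steps",
                    res, tol, iter))
  P
}
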