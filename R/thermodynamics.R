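#' Generalized chemical potential of a directed edge
#'
#' \eqn{A_{ji} = \ln\left(\frac{T_{ji}P_j}{T_{ij}P_i}\right)}: the
#' thermodynamic force driving probability from state `j` to state `i`
#' (voltage, in the circuit analogy, with the flux as the current). Zero on
#' detailed-balanced edges; antisymmetric where finite. A one-way edge
#' (one of the two directed weights zero) has infinite affinity, returned
#' as `Inf`/`-Inf`.
#'
#' @param T row-stochastic transition matrix.
#' @param P probability vector.
#' @param i,j canonical (0-based) state indices.
#' @return the affinity \eqn{A_{ji}} (log ratio of directed probability
#'   flows j->i over i->j).
#' @export
chemical_potential <- function(T, P, i, j) {
  ii <- as.integer(i) + 1L; jj <- as.integer(j) + 1L
  if ((T[jj, ii] == 0 || P[jj] == 0) && (T[ii, jj] == 0 || P[ii] == 0))
    stop("edge carries no probability flow in either direction")
  # logs taken factor-wise: the products T*P can underflow double precision
  # on strongly suppressed edges even when every factor is positive
  (log(T[jj, ii]) + log(P[jj])) - (log(T[ii, jj]) + log(P[ii]))
}

#' Shannon entropy of a distribution
#'
#' \eqn{S = -\sum_i P_i \ln P_i} in nats, with the convention
#' \eqn{0 \ln 0 = 0}.
#'
#' @param P probability vector.
#' @return nonnegative entropy in nats.
#' @export
system_entropy <- function(P) {
  check_probability(P)
  P <- P[P > 0]
  -sum(P * log(P))
}

#' Steady-state entropy production rate
#'
#' The total dissipation rate of the stationary chain,
#' \deqn{\frac{dS_{tot}}{dt} = \sum_{i,j} T_{ji} P_j
#'       \ln\frac{T_{ji}P_j}{T_{ij}P_i}
#'       = \sum_{i<j} F_{ji} A_{ji} \ \ge 0,}
#' in nats per time step. It vanishes exactly when detailed balance holds
#' (every pairwise term is of the form \eqn{(a-b)\ln(a/b) \ge 0}).
#'
#' Edges carrying probability in one direction only would contribute a
#' divergent term; these are segregated rather than silently dropped: the
#' finite part is always reported, `rate` is `Inf` when divergent edges
#' with positive flux exist, and the offending edges are listed.
#'
#' @inheritParams steady_state_flux
#' @param log_T optional element-wise log of `T` (see
#'   [log_transition_matrix()]). For sharp-response kernels many entries of
#'   `T` underflow to exact zero in double precision; supplying the
#'   factor-wise log keeps their true magnitude and their (finite, large)
#'   affinities. Without it, zeros of `T` are taken at face value as
#'   one-way edges.
#' @return list with `rate` (the entropy production rate; `Inf` if any
#'   strictly one-way edge carries flux), `finite_part`,
#'   `n_divergent_edges`, and `divergent_edges` (two-column matrix of
#'   0-based ordered state pairs).
#' @export
entropy_production_rate <- function(T, P, tol = 1e-8, log_T = NULL) {
  check_stationary(T, P, tol)
  if (is.null(log_T)) {
    pos <- T > 0
    log_T <- matrix(-Inf, nrow(T), ncol(T))
    log_T[pos] <- log(T[pos])
  }
  logW <- log_T + ifelse(P > 0, log(P), -Inf)   # row-wise: + log P_i
  W <- exp(logW)                               # T_ij P_i, flow i -> j
  twoway <- is.finite(logW) & is.finite(t(logW))
  diag(twoway) <- FALSE
  finite_part <- sum(W[twoway] * (logW[twoway] - t(logW)[twoway]))
  oneway <- which(is.finite(logW) & !is.finite(t(logW)), arr.ind = TRUE)
  list(rate = if (nrow(oneway) > 0L) Inf else finite_part,
       finite_part = finite_part,
       n_divergent_edges = nrow(oneway),
       divergent_edges = oneway - 1L)
}

#' Thermodynamic summary of a stationary chain
#'
#' @inheritParams steady_state_flux
#' @return an object of class `thermo_summary`: list with `entropy`
#'   (system Shannon entropy, nats), `ep_rate` (entropy production rate,
#'   nats/step), `finite_part` and `n_divergent_edges`.
#' @export
thermo_summary <- function(T, P, tol = 1e-8, log_T = NULL) {
  ep <- entropy_production_rate(T, P, tol, log_T = log_T)
  structure(list(entropy = system_entropy(P), ep_rate = ep$rate,
                 finite_part = ep$finite_part,
                 n_divergent_edges = ep$n_divergent_edges),
            class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat(sprintf("thermo_summary: S = %.5f nats, dS_tot/dt = %.6g nats/step (%d divergent edges)\n",
              x$entropy, x$ep_rate, x$n_divergent_edges))
  invisible(x)
}
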