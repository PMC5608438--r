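#' Steady-state probability flux between states
#'
#' The net flux on the pair (i, j) at stationarity is
#' \eqn{F_{ij} = -T_{ij} P_i + T_{ji} P_j} (positive when probability flows
#' j to i). `F` is antisymmetric, and each row sums to zero because `P` is
#' stationary. All off-diagonal pairs where detailed balance
#' (\eqn{T_{ij}P_i = T_{ji}P_j}) holds carry zero net flux.
#'
#' @param T row-stochastic transition matrix.
#' @param P stationary probability vector for `T`.
#' @param tol stationarity check tolerance.
#' @return the antisymmetric flux matrix `F`.
#' @export
steady_state_flux <- function(T, P, tol = 1e-8) {
  check_stationary(T, P, tol)
  Pi <- T * P                 # Pi[i, j] = T_ij * P_i (column recycling of P)
  t(Pi) - Pi
}

check_stationary <- function(T, P, tol = 1e-8) {
  check_row_stochastic(T)
  check_probability(P, nrow(T))
  res <- max(abs(as.vector(t(T) %*% P) - P))
  if (res > tol)
    stop(sprintf("P is not stationary for T (residual %.3g > %.3g)", res, tol))
  invisible(res)
}

#' Detailed-balance / irreversible decomposition of the kernel
#'
#' Splits the rate matrix `M` (off-diagonal `M_ij = T_ij`, diagonal
#' `-sum_j T_ij`) into `M = C + D`:
#' \deqn{C_{ij} = \max\{T_{ij}P_i - T_{ji}P_j, 0\}/P_i, \quad
#'       D_{ij} = \min\{T_{ij}P_i, T_{ji}P_j\}/P_i \ (i \neq j),}
#' with diagonals minus the row sums. Both parts are stationary under `P`
#' (\eqn{C'P = D'P = 0}); `D` satisfies detailed balance and `C` is purely
#' one-way (if \eqn{C_{ij}P_i > 0} then \eqn{C_{ji}P_j = 0}) and carries
#' all the curl flux.
#'
#' @inheritParams steady_state_flux
#' @return list with matrices `C` and `D`.
#' @export
decompose_CD <- function(T, P, tol = 1e-8) {
  check_stationary(T, P, tol)
  N <- nrow(T)
  Pi <- T * P
  if (any(P <= 0 & (rowSums(Pi) > 0 | colSums(Pi) > 0)))
    stop("states with zero stationary probability carry flux; decomposition undefined")
  Psafe <- ifelse(P > 0, P, 1)
  C <- pmax(Pi - t(Pi), 0) / Psafe
  D <- pmin(Pi, t(Pi)) / Psafe
  diag(C) <- 0; diag(D) <- 0
  diag(C) <- -rowSums(C)
  diag(D) <- -rowSums(D)
  list(C = C, D = D)
}

#' One-way flux matrix J
#'
#' \eqn{J_{ij} = C_{ij} P_i = \max\{T_{ij}P_i - T_{ji}P_j, 0\}} with zero
#' diagonal: the nonnegative irreversible flux on each directed edge. At
#' stationarity in-flux equals out-flux at every state
#' (\eqn{\sum_i J_{ij} = \sum_i J_{ji}}), which is what makes the loop
#' decomposition of [extract_loops()] possible.
#'
#' @inheritParams steady_state_flux
#' @return the nonnegative matrix `J`.
#' @export
flux_matrix <- function(T, P, tol = 1e-8) {
  check_stationary(T, P, tol)
  Pi <- T * P
  J <- pmax(Pi - t(Pi), 0)
  diag(J) <- 0
  J
}

#' Peel the one-way flux into closed loops
#'
#' Decomposes a balanced nonnegative flux matrix into directed cycles:
#' repeatedly walk along positive entries until a state repeats, record the
#' enclosed cycle with flux value `r` = minimum edge flux on it, subtract
#' `r` along the cycle, until the matrix is exhausted. The edge-wise sum of
#' the returned loops reconstructs `J` (up to the numerical floor).
#'
#' The peeling order is not unique; the default policy starts each search
#' at the smallest-index state with positive out-flux and follows the
#' largest outgoing flux (ties to the smallest target index). Only
#' policy-invariant quantities (total flux, reconstruction, the dominant
#' native loop when it is edge-disjoint) should be interpreted.
#'
#' @param J nonnegative flux matrix with balanced in/out sums per state
#'   (see [flux_matrix()]).
#' @param floor entries below this are zeroed before and during peeling
#'   (guarantees termination).
#' @param conservation_tol tolerance for the balance precondition.
#' @return an object of class `flux_loops`: list with `states` (list of
#'   integer vectors of canonical 0-based state indices, each an ordered
#'   cycle without the closing repeat), `flux` (numeric vector), and
#'   `total_flux`.
#' @export
extract_loops <- function(J, floor = 1e-14, conservation_tol = 1e-9) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("J must be a square matrix")
  if (any(J < 0)) stop("J must be nonnegative")
  imbalance <- max(abs(rowSums(J) - colSums(J)))
  scale <- max(sum(J), 1e-300)
  if (imbalance > conservation_tol * max(1, scale) && imbalance > conservation_tol)
    stop(sprintf("J is not flux-conserving (imbalance %.3g)", imbalance))
  res <- peel_loops_cpp(J, floor)
  states <- lapply(res$states, function(v) as.integer(v - 1L))
  structure(list(states = states, flux = as.numeric(res$flux),
                 total_flux = sum(res$flux)),
            class = "flux_loops")
}

#' @export
print.flux_loops <- function(x, ...) {
  cat(sprintf("flux_loops: %d loops, total flux %.6g\n",
              length(x$flux), x$total_flux))
  invisible(x)
}

#' Rebuild a flux matrix from loops (reconstruction check)
#'
#' @param loops a `flux_loops` object.
#' @param n_states matrix dimension.
#' @return the edge-wise sum of the loops as a matrix.
#' @export
loops_to_matrix <- function(loops, n_states) {
  J <- matrix(0, n_states, n_states)
  for (k in seq_along(loops$flux)) {
    cyc <- loops$states[[k]] + 1L
    m <- length(cyc)
    e <- cbind(cyc, cyc[c(seq_len(m)[-1L], 1L)])
    J[e] <- J[e] + loops$flux[k]
  }
  J
}

# does the loop equal the reference cycle up to rotation (direction matters)?
same_cycle <- function(loop, ref) {
  m <- length(ref)
  if (length(loop) != m || !all(sort(loop) == sort(ref))) return(FALSE)
  k <- which(loop == ref[1L])
  if (length(k) != 1L) return(FALSE)
  all(c(loop[k:m], loop[seq_len(k - 1L)]) == ref)
}

#' Flux landscape over the loop ensemble
#'
#' Normalizes the loop fluxes into loop probabilities
#' \eqn{P_{flux} = flux_{loop} / \sum flux} and loop potentials
#' \eqn{U_{flux} = -\ln P_{flux}}. If a native path is supplied, the native
#' loop(s) are identified and the robustness ratio of the flux spectrum is
#' computed exactly as for the potential landscape, with the native loops
#' as the native set. A dominant native loop (minimal \eqn{U_{flux}})
#' standing far below the rest is the signature of a robust limit cycle.
#'
#' @param loops a `flux_loops` object from [extract_loops()].
#' @param native_path optional [native_path()]; matched against loops as a
#'   cyclic sequence up to rotation (`"exact"`), or any loop whose state
#'   set is a subset of the native path's states (`"subset"`).
#' @param native_match matching rule, see above.
#' @param convention gap convention passed to the robustness-ratio core.
#' @return an object of class `flux_landscape`: list with `P_flux`,
#'   `U_flux`, `native_loops` (indices into the loop list, possibly
#'   empty), `RR_flux` (`NA` if no native loop found), plus gap/roughness.
#' @export
flux_landscape <- function(loops, native_path = NULL,
                           native_match = c("exact", "subset"),
                           convention = c("native-mean", "native-min",
                                          "global-min")) {
  native_match <- match.arg(native_match)
  convention <- match.arg(convention)
  if (length(loops$flux) == 0L)
    stop("empty flux landscape: the chain is detailed balanced (no loops)")
  P_flux <- loops$flux / sum(loops$flux)
  U_flux <- -log(P_flux)
  native_loops <- integer()
  RR_flux <- NA_real_; gap <- NA_real_; roughness <- NA_real_
  if (!is.null(native_path)) {
    ref <- native_path$indices
    native_loops <- switch(native_match,
      exact  = which(vapply(loops$states, same_cycle, logical(1), ref = ref)),
      subset = which(vapply(loops$states, function(s) all(s %in% ref), logical(1))))
    if (length(native_loops) > 0L) {
      core <- rr_core(U_flux, native_loops, convention)
      RR_flux <- core$RR; gap <- core$gap; roughness <- core$roughness
    }
  }
  structure(list(P_flux = P_flux, U_flux = U_flux,
                 native_loops = native_loops, RR_flux = RR_flux,
                 gap = gap, roughness = roughness,
                 convention = convention, native_match = native_match),
            class = "flux_landscape")
}

#' @export
print.flux_landscape <- function(x, ...) {
  cat(sprintf("flux_landscape: %d loops", length(x$P_flux)))
  if (length(x$native_loops))
    cat(sprintf("; native loop P_flux = %.4g, RR_flux = %.5f",
                sum(x$P_flux[x$native_loops]), x$RR_flux))
  cat("\n")
  invisible(x)
}

#' Loop statistics of a stochastic trajectory
#'
#' Scans a state-index trajectory left to right keeping the current open
#' path; when a state on the open path is revisited, the enclosed loop is
#' recorded and excised, and the scan continues. Loops are counted up to
#' rotation (direction preserved). The empirical loop fraction
#' `count / total` converges to the matrix-based loop probability
#' [flux_landscape()] as the trajectory grows.
#'
#' @param trajectory integer vector of canonical (0-based) state indices,
#'   or a trajectory object from [simulate_trajectory()].
#' @return data.frame with columns `loop` (dash-separated canonical cycle,
#'   rotated to start at its smallest state), `n_states`, `count`,
#'   `p_flux` (empirical fraction), sorted by count descending.
#' @export
trajectory_loop_statistics <- function(trajectory) {
  if (inherits(trajectory, "boolean_trajectory")) trajectory <- trajectory$states
  traj <- as.integer(trajectory)
  counts <- new.env(parent = emptyenv())
  path <- integer(2 * length(traj))     # open path stack
  top <- 0L
  pos <- new.env(parent = emptyenv())   # state -> position on stack
  for (s in traj) {
    key <- as.character(s)
    p <- pos[[key]]
    if (!is.null(p)) {
      cyc <- path[p:top]
      if (length(cyc) >= 2L) {   # self-transitions are not flux loops
        # canonical rotation: start at the minimum state
        k <- which.min(cyc)
        cyc <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
        ckey <- paste(cyc, collapse = "-")
        counts[[ckey]] <- (if (is.null(counts[[ckey]])) 0L else counts[[ckey]]) + 1L
      }
      # excise the loop: pop back to p (s stays at position p)
      for (q in seq.int(p + 1L, length.out = top - p))
        rm(list = as.character(path[q]), envir = pos)
      top <- p
    } else {
      top <- top + 1L
      path[top] <- s
      pos[[key]] <- top
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L)
    return(data.frame(loop = character(), n_states = integer(),
                      count = integer(), p_flux = numeric()))
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  ns <- vapply(strsplit(keys, "-", fixed = TRUE), length, integer(1))
  out <- data.frame(loop = keys, n_states = ns, count = cnt,
                    p_flux = cnt / sum(cnt), row.names = NULL)
  out[order(-out$count), , drop = FALSE]
}

#' Canonical key of a cycle (for matching against trajectory statistics)
#'
#' @param states integer vector of 0-based state indices forming a cycle.
#' @return dash-separated key rotated to start at the smallest state.
#' @export
loop_key <- function(states) {
  k <- which.min(states)
  paste(c(states[k:length(states)], states[seq_len(k - 1L)]), collapse = "-")
}
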