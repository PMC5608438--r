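#' Potential landscape from a stationary distribution
#'
#' The dimensionless potential of state `i` is \eqn{U_i = -\ln P_i^{ss}}.
#' States with zero probability (unreachable, e.g. at `c = 0`) get `Inf`
#' and are excluded from all landscape statistics downstream. Probabilities
#' below 1e-300 are treated as zero before taking logs.
#'
#' @param P stationary probability vector.
#' @return numeric vector of potentials (same ordering as `P`).
#' @export
potential_from_probability <- function(P) {
  check_probability(P)
  P <- pmax(P, 0)
  P[P < 1e-300] <- 0
  U <- rep(Inf, length(P))
  U[P > 0] <- -log(P[P > 0])
  U
}

# shared core: gap / roughness / ratio over a set of potentials
rr_core <- function(U, native_pos, convention) {
  finite <- is.finite(U)
  if (!any(finite)) stop("no finite potentials")
  if (!all(finite[native_pos]))
    stop("native states must have finite potential")
  Uf <- U[finite]
  mean_U <- mean(Uf)
  roughness <- sqrt(mean(Uf^2) - mean_U^2)
  U_native <- switch(convention,
    "native-mean" = mean(U[native_pos]),
    "native-min"  = min(U[native_pos]),
    "global-min"  = min(Uf))
  gap <- abs(U_native - mean_U)
  if (roughness <= 0)
    stop("degenerate flat landscape: roughness is zero, RR undefined")
  list(U_native = U_native, mean_U = mean_U, roughness = roughness,
       gap = gap, RR = gap / roughness)
}

#' Robustness ratio of a potential landscape
#'
#' The robustness ratio \eqn{RR = \delta U / \Delta U} measures the degree
#' of funneling: \eqn{\delta U = |U_m - \langle U\rangle|} is the gap
#' between the native reference potential and the landscape average, and
#' \eqn{\Delta U = \sqrt{\langle U^2\rangle - \langle U\rangle^2}} is the
#' roughness (population standard deviation). Moments run over all states
#' with finite potential. `RR > 1` indicates a landscape funneled towards
#' the native states.
#'
#' For a multi-state native set (an oscillation path) the reference
#' \eqn{U_m} is a convention: `"native-mean"` (default; mean potential of
#' the native states), `"native-min"`, or `"global-min"`.
#'
#' @param U potential vector (see [potential_from_probability()]).
#' @param native canonical state indices (0-based) of the native set.
#' @param convention gap convention, see Details.
#' @return an object of class `landscape_summary`: list with `U`,
#'   `native`, `U_native`, `mean_U`, `roughness`, `gap`, `RR`,
#'   `convention`.
#' @export
robustness_ratio <- function(U, native,
                             convention = c("native-mean", "native-min",
                                            "global-min")) {
  convention <- match.arg(convention)
  native <- as.integer(native)
  if (length(native) == 0L) stop("native set must be nonempty")
  if (any(native < 0L) || any(native >= length(U)))
    stop("native state index out of range")
  core <- rr_core(U, native + 1L, convention)
  structure(c(list(U = U, native = native, convention = convention), core),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf(paste0("landscape_summary (%d states, %d native)\n",
                     "  gap dU = %.5f   roughness DU = %.5f   RR = %.5f  [%s]\n"),
              length(x$U), length(x$native), x$gap, x$roughness, x$RR,
              x$convention))
  invisible(x)
}

#' Landscape spectrum
#'
#' Orders all states by increasing potential, flagging the native ones —
#' the tabular form of the landscape-spectrum plot.
#'
#' @inheritParams robustness_ratio
#' @return data.frame with columns `rank`, `state_index` (0-based), `U`,
#'   `is_native`, sorted by `U` ascending.
#' @export
landscape_spectrum <- function(U, native = integer()) {
  native <- as.integer(native)
  ord <- order(U)
  data.frame(rank = seq_along(U),
             state_index = ord - 1L,
             U = U[ord],
             is_native = (ord - 1L) %in% native)
}

#' Occupation probability of a state set
#'
#' @param P probability vector.
#' @param states canonical state indices (0-based).
#' @return the summed probability (e.g. P_circle for a native path).
#' @export
state_set_probability <- function(P, states) {
  states <- as.integer(states)
  if (any(states < 0L) || any(states >= length(P)))
    stop("state index out of range")
  sum(P[states + 1L])
}
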