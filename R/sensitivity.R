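#' Network perturbations
#'
#' A perturbation is one of: `delete_edge` (zero one signed interaction),
#' `add_edge` (set a currently absent interaction to `sign`),
#' `flip_edge_sign`, or `delete_node` (zero the node's row and column).
#'
#' @param kind perturbation type.
#' @param source,target node names (for edge perturbations).
#' @param node node name (for `delete_node`).
#' @param sign +1 or -1 (for `add_edge`).
#' @return an object of class `perturbation`.
#' @export
perturbation <- function(kind = c("delete_edge", "add_edge",
                                  "flip_edge_sign", "delete_node"),
                         source = NULL, target = NULL, node = NULL,
                         sign = NULL) {
  kind <- match.arg(kind)
  if (kind == "delete_node") {
    if (is.null(node)) stop("delete_node needs a node name")
  } else {
    if (is.null(source) || is.null(target))
      stop(kind, " needs source and target")
    if (kind == "add_edge" && (is.null(sign) || !sign %in% c(-1, 1)))
      stop("add_edge needs sign +1 or -1")
  }
  structure(list(kind = kind, source = source, target = target,
                 node = node, sign = sign),
            class = "perturbation")
}

#' @rdname perturbation
#' @param net a `regulatory_network`.
#' @param pert a `perturbation`.
#' @return `apply_perturbation`: a new `regulatory_network` (the original
#'   is unchanged).
#' @export
apply_perturbation <- function(net, pert) {
  a <- net$interactions
  if (pert$kind == "delete_node") {
    i <- match(pert$node, net$nodes)
    if (is.na(i)) stop("unknown node: ", pert$node)
    a[i, ] <- 0L
    a[, i] <- 0L
  } else {
    j <- match(pert$source, net$nodes)
    i <- match(pert$target, net$nodes)
    if (is.na(i) || is.na(j))
      stop("unknown node in edge ", pert$source, " -> ", pert$target)
    cur <- a[i, j]
    a[i, j] <- switch(pert$kind,
      delete_edge = { if (cur == 0L) stop("edge does not exist") else 0L },
      flip_edge_sign = { if (cur == 0L) stop("edge does not exist") else -cur },
      add_edge = { if (cur != 0L) stop("edge already exists") else as.integer(pert$sign) })
  }
  regulatory_network(net$nodes, a, g0_state = net$g0_state,
                     checkpoint = net$checkpoint, thresholds = net$thresholds)
}

#' Landscape and flux metrics of one network
#'
#' Runs the full pipeline (kernel, steady state, potentials, flux loops,
#' dissipation) and returns the stability metrics used by the sensitivity
#' analysis: the potential-landscape robustness ratio `RR`, the stationary
#' probability `P_G1` of the resting state, the flux-spectrum robustness
#' ratio `RR_flux` (0 with `flux_flag = TRUE` when no native loop
#' survives), the native-path occupation `P_circle`, and the entropy
#' production rate.
#'
#' @inheritParams build_transition_matrix
#' @param native_path a [native_path()].
#' @param convention gap convention for both robustness ratios.
#' @param native_match native-loop matching rule, see [flux_landscape()].
#' @return an object of class `metric_triple` (a list).
#' @export
evaluate_metrics <- function(net, params, native_path,
                             convention = "native-mean",
                             native_match = "exact",
                             threshold_scaling = c("integer", "half")) {
  T <- build_transition_matrix(net, params,
                               threshold_scaling = match.arg(threshold_scaling))
  P <- solve_steady_state(T)
  U <- potential_from_probability(P)
  RR <- robustness_ratio(U, native_path$indices, convention = convention)$RR
  P_G1 <- if (!is.null(net$g0_state))
    P[encode_state(net$g0_state) + 1L] else NA_real_
  loops <- extract_loops(flux_matrix(T, P))
  RR_flux <- 0; flux_flag <- TRUE
  if (length(loops$flux) > 0L) {
    fl <- flux_landscape(loops, native_path, native_match = native_match,
                         convention = convention)
    if (length(fl$native_loops) > 0L && is.finite(fl$RR_flux)) {
      RR_flux <- fl$RR_flux
      flux_flag <- FALSE
    }
  }
  log_T <- log_transition_matrix(net, params,
                                 threshold_scaling = threshold_scaling)
  ep <- entropy_production_rate(T, P, log_T = log_T)
  structure(list(RR = RR, P_G1 = P_G1, RR_flux = RR_flux,
                 P_circle = state_set_probability(P, native_path$indices),
                 ep_rate = ep$finite_part, flux_flag = flux_flag),
            class = "metric_triple")
}

#' @export
print.metric_triple <- function(x, ...) {
  cat(sprintf("metric_triple: RR = %.5f, P_G1 = %.5g, RR_flux = %.5f%s\n",
              x$RR, x$P_G1, x$RR_flux,
              if (x$flux_flag) " (flagged: no native loop)" else ""))
  invisible(x)
}

# edges of a network ordered lexicographically by (source, target) name --
# the documented, reproducible tie-break order
edge_list <- function(net) {
  idx <- which(net$interactions != 0L, arr.ind = TRUE)
  src <- net$nodes[idx[, 2L]]
  dst <- net$nodes[idx[, 1L]]
  ord <- order(src, dst, method = "radix")
  data.frame(source = src[ord], target = dst[ord],
             sign = net$interactions[idx[ord, , drop = FALSE]],
             row = idx[ord, 1L], col = idx[ord, 2L])
}

#' Edge sensitivity ranking by total evaluation score (TES)
#'
#' Deletes each edge in turn, recomputes the three stability metrics (RR,
#' P_G1, RR_flux), and scores each edge per metric by the rank of its
#' difference from the wild type: the edge with the largest difference
#' scores `n_edges`, the smallest scores 1. The total evaluation score is
#' the sum of the three per-metric scores; the robustness rank orders TES
#' descending (rank 1 = most impactful edge). Ties are broken by the
#' lexicographic (source, target) edge order, so the ranking is
#' reproducible and independent of matrix storage order.
#'
#' @inheritParams evaluate_metrics
#' @param difference `"absolute"` (default) ranks `|mutant - wildtype|`;
#'   `"signed"` ranks the drop `wildtype - mutant` (rewarding edges whose
#'   removal destabilizes the network).
#' @param progress print one line per edge while sweeping.
#' @return an object of class `tes_ranking`: data.frame with one row per
#'   edge (`source`, `target`, `sign`, the three metric differences,
#'   per-metric scores, `TES`, `robustness_rank`), ordered by
#'   `robustness_rank`; the wild-type metrics are in
#'   `attr(x, "wild_type")`.
#' @export
rank_edges_TES <- function(net, params, native_path,
                           difference = c("absolute", "signed"),
                           convention = "native-mean",
                           native_match = "exact",
                           threshold_scaling = c("integer", "half"),
                           progress = FALSE) {
  difference <- match.arg(difference)
  threshold_scaling <- match.arg(threshold_scaling)
  edges <- edge_list(net)
  if (nrow(edges) < 2L) stop("need at least 2 edges to rank")
  wt <- evaluate_metrics(net, params, native_path, convention = convention,
                         native_match = native_match,
                         threshold_scaling = threshold_scaling)
  m <- matrix(NA_real_, nrow(edges), 3L,
              dimnames = list(NULL, c("RR", "P_G1", "RR_flux")))
  for (k in seq_len(nrow(edges))) {
    mut <- apply_perturbation(net, perturbation("delete_edge",
                                                source = edges$source[k],
                                                target = edges$target[k]))
    mm <- evaluate_metrics(mut, params, native_path, convention = convention,
                           native_match = native_match,
                           threshold_scaling = threshold_scaling)
    m[k, ] <- c(mm$RR, mm$P_G1, mm$RR_flux)
    if (progress)
      message(sprintf("%s -> %s: RR %.4f P_G1 %.4g RR_flux %.4f",
                      edges$source[k], edges$target[k],
                      mm$RR, mm$P_G1, mm$RR_flux))
  }
  wtv <- c(wt$RR, wt$P_G1, wt$RR_flux)
  d <- if (difference == "absolute") abs(sweep(m, 2L, wtv))
       else sweep(-m, 2L, -wtv)               # wildtype - mutant
  # ranks on the lexicographically ordered edges; ties.method = "first"
  # makes the tie-break the documented edge order
  scores <- apply(d, 2L, rank, ties.method = "first")
  TES <- as.integer(rowSums(scores))
  rob <- integer(nrow(edges))
  rob[order(-TES)] <- seq_len(nrow(edges))    # stable: ties by edge order
  out <- data.frame(edges[, c("source", "target", "sign")],
                    d_RR = d[, 1L], d_PG1 = d[, 2L], d_RRflux = d[, 3L],
                    RR_score = scores[, 1L], PG1_score = scores[, 2L],
                    RRflux_score = scores[, 3L],
                    TES = TES, robustness_rank = rob)
  out <- out[order(out$robustness_rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tes_ranking", "data.frame"),
            wild_type = wt, difference = difference)
}

#' Extract the backbone subnetwork
#'
#' Keeps the `n_keep` top edges of a TES ranking (robustness rank 1..
#' `n_keep`) and zeroes the rest. The result records in
#' `attr(x, "path_survives")` whether the deterministic biological path of
#' `native_path` still runs unchanged in the subnetwork.
#'
#' @param net the original `regulatory_network`.
#' @param ranking a `tes_ranking` from [rank_edges_TES()].
#' @param n_keep number of top edges to keep (0..n_edges).
#' @param native_path optional [native_path()] for the survival check.
#' @return the backbone `regulatory_network`.
#' @export
backbone_extract <- function(net, ranking, n_keep, native_path = NULL) {
  keep <- ranking[ranking$robustness_rank <= n_keep, , drop = FALSE]
  a <- matrix(0L, n_nodes(net), n_nodes(net),
              dimnames = dimnames(net$interactions))
  for (k in seq_len(nrow(keep))) {
    i <- match(keep$target[k], net$nodes)
    j <- match(keep$source[k], net$nodes)
    a[i, j] <- as.integer(keep$sign[k])
  }
  sub <- regulatory_network(net$nodes, a, g0_state = net$g0_state,
                            checkpoint = net$checkpoint,
                            thresholds = net$thresholds)
  survives <- NA
  if (!is.null(native_path)) {
    k <- nrow(native_path$states)
    tr <- deterministic_trajectory(sub, native_path$states[1L, ], k - 1L)
    survives <- all(tr == native_path$states)
  }
  attr(sub, "path_survives") <- survives
  sub
}

#' Default perturbation set (single mutations)
#'
#' All single-edge deletions, all single-edge sign flips, and all
#' single-node deletions.
#'
#' @param net a `regulatory_network`.
#' @return list of [perturbation()] objects.
#' @export
default_perturbation_set <- function(net) {
  edges <- edge_list(net)
  dels <- lapply(seq_len(nrow(edges)), function(k)
    perturbation("delete_edge", source = edges$source[k], target = edges$target[k]))
  flips <- lapply(seq_len(nrow(edges)), function(k)
    perturbation("flip_edge_sign", source = edges$source[k], target = edges$target[k]))
  nodes <- lapply(net$nodes, function(nm) perturbation("delete_node", node = nm))
  c(dels, flips, nodes)
}

#' Metric scatter over a perturbation set
#'
#' Evaluates every perturbation independently and returns the raw material
#' of the stability scatter plots: native-cycle occupation `P_circle`
#' versus `RR`, `RR_flux`, `P_G1` and dissipation. The wild type is the
#' first row.
#'
#' @inheritParams evaluate_metrics
#' @param perturbations list of [perturbation()]s; default
#'   [default_perturbation_set()].
#' @return data.frame with columns `label`, `kind`, `P_circle`, `P_G1`,
#'   `RR`, `RR_flux`, `ep_rate`, `flux_flag`.
#' @export
perturbation_scatter <- function(net, params, native_path,
                                 perturbations = NULL,
                                 convention = "native-mean",
                                 native_match = "exact",
                                 threshold_scaling = c("integer", "half")) {
  threshold_scaling <- match.arg(threshold_scaling)
  if (is.null(perturbations)) perturbations <- default_perturbation_set(net)
  lab <- function(p) switch(p$kind,
    delete_node = paste0("delete_node:", p$node),
    paste0(p$kind, ":", p$source, "->", p$target))
  nets <- c(list(net), lapply(perturbations, apply_perturbation, net = net))
  labels <- c("wild_type", vapply(perturbations, lab, character(1)))
  kinds <- c("none", vapply(perturbations, `[[`, character(1), "kind"))
  rows <- lapply(seq_along(nets), function(k) {
    mm <- evaluate_metrics(nets[[k]], params, native_path,
                           convention = convention,
                           native_match = native_match,
                           threshold_scaling = threshold_scaling)
    data.frame(label = labels[k], kind = kinds[k],
               P_circle = mm$P_circle, P_G1 = mm$P_G1, RR = mm$RR,
               RR_flux = mm$RR_flux, ep_rate = mm$ep_rate,
               flux_flag = mm$flux_flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
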