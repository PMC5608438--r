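#' Construct a signed Boolean regulatory network
#'
#' A regulatory network is a set of named nodes plus a signed interaction
#' matrix `a` with `a[i, j]` the effect of node `j` on node `i`
#' (+1 activation, -1 inhibition, 0 none). The total input of node `i` in
#' global state `s` is \eqn{I_i = \sum_j a_{ij} s_j}.
#'
#' Some Boolean models give individual nodes a non-zero activation threshold
#' \eqn{\theta_i}: the node compares its total input against \eqn{\theta_i}
#' rather than 0. The effective input used by all update rules is
#' \eqn{I_i - \theta_i}. Thresholds default to 0, in which case the classic
#' rule (on if \eqn{I > 0}, off if \eqn{I < 0}, hold at \eqn{I = 0}) is
#' recovered exactly.
#'
#' @param nodes character vector of unique node names.
#' @param interactions n x n numeric matrix with entries in `{-1, 0, 1}`;
#'   row = target, column = source.
#' @param g0_state optional resting-state bit vector (length n). When set,
#'   the checkpoint node receives the cycling activation `gamma` whenever the
#'   global state equals `g0_state` (see [model_parameters()]).
#' @param checkpoint index (1-based) of the checkpoint node excited from the
#'   resting state; default 1.
#' @param thresholds optional numeric vector of per-node activation
#'   thresholds; default all 0.
#' @return an object of class `regulatory_network`.
#' @seealso [fission_yeast_fixture()], [load_network()], [deterministic_update()]
#' @export
regulatory_network <- function(nodes, interactions, g0_state = NULL,
                               checkpoint = 1L, thresholds = NULL) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n < 1L) stop("network needs at least one node")
  if (anyDuplicated(nodes)) stop("node names must be unique")
  interactions <- as.matrix(interactions)
  if (!all(dim(interactions) == c(n, n)))
    stop("interactions must be an n x n matrix matching the node list")
  if (!all(interactions %in% c(-1, 0, 1)))
    stop("interaction entries must be in {-1, 0, +1}")
  storage.mode(interactions) <- "integer"
  dimnames(interactions) <- list(nodes, nodes)
  if (is.null(thresholds)) thresholds <- numeric(n)
  if (length(thresholds) != n) stop("thresholds must have one entry per node")
  thresholds <- as.numeric(thresholds)
  checkpoint <- as.integer(checkpoint)
  if (checkpoint < 1L || checkpoint > n) stop("invalid checkpoint index")
  if (!is.null(g0_state)) {
    g0_state <- check_bits(g0_state, n)
  }
  structure(
    list(nodes = nodes, interactions = interactions, g0_state = g0_state,
         checkpoint = checkpoint, thresholds = thresholds),
    class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d signed edges\n",
              n_nodes(x), sum(x$interactions != 0L)))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (!is.null(x$g0_state))
    cat("resting (G0) state index:", encode_state(x$g0_state),
        " checkpoint:", x$nodes[x$checkpoint], "\n")
  invisible(x)
}

#' @rdname regulatory_network
#' @param net a `regulatory_network`.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname regulatory_network
#' @export
n_states <- function(net) 2L^n_nodes(net)

check_bits <- function(bits, n = NULL) {
  bits <- as.integer(bits)
  if (!is.null(n) && length(bits) != n)
    stop(sprintf("state must have %d bits, got %d", n, length(bits)))
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("state entries must be 0 or 1")
  bits
}

#' Encode and decode network states
#'
#' A global state is a bit vector in node order; its canonical index is
#' \eqn{\sum_i s_i 2^{i-1}} (node 1 = least significant bit), an integer in
#' `[0, 2^n)`. `encode_state()` and `decode_state()` are exact inverses.
#'
#' @param bits binary vector (entries 0/1).
#' @return `encode_state`: the canonical state index (0-based).
#' @examples
#' encode_state(c(1, 0, 1)) # 5
#' decode_state(5, 3)
#' @export
encode_state <- function(bits) {
  bits <- check_bits(bits)
  if (length(bits) > 30L) stop("encode_state supports at most 30 nodes")
  sum(bits * 2^(seq_along(bits) - 1L))
}

#' @rdname encode_state
#' @param index canonical state index in `[0, 2^n)`.
#' @param n_nodes number of nodes.
#' @return `decode_state`: the bit vector of length `n_nodes`.
#' @export
decode_state <- function(index, n_nodes) {
  index <- as.integer(index)
  if (index < 0L || index >= 2L^n_nodes) stop("state index out of range")
  as.integer(bitwAnd(bitwShiftR(index, seq_len(n_nodes) - 1L), 1L))
}

# all 2^n states as an N x n bit matrix, row k+1 = state index k
state_table <- function(n_nodes) {
  N <- 2L^n_nodes
  m <- matrix(0L, N, n_nodes)
  idx <- 0:(N - 1L)
  for (i in seq_len(n_nodes))
    m[, i] <- bitwAnd(bitwShiftR(idx, i - 1L), 1L)
  m
}

#' Total input of a node
#'
#' Returns \eqn{I_i = \sum_j a_{ij} s_j}, the signed sum of active
#' regulators of node `i` in state `s` (thresholds are not subtracted;
#' see [regulatory_network()] for the effective input).
#'
#' @param net a `regulatory_network`.
#' @param state bit vector (length `n_nodes(net)`).
#' @param i node index (1-based) or node name.
#' @return integer total input.
#' @export
total_input <- function(net, state, i) {
  state <- check_bits(state, n_nodes(net))
  if (is.character(i)) i <- match(i, net$nodes)
  if (is.na(i) || i < 1L || i > n_nodes(net)) stop("invalid node index")
  as.integer(sum(net$interactions[i, ] * state))
}

#' Synchronous deterministic Boolean update
#'
#' All nodes update simultaneously by the threshold rule on the effective
#' input \eqn{h_i = I_i - \theta_i}: the new bit is 1 if \eqn{h_i > 0},
#' 0 if \eqn{h_i < 0}, and holds the current bit if \eqn{h_i = 0}.
#' This is the zero-noise limit of the stochastic kernel (no basal flips,
#' no checkpoint excitation).
#'
#' @inheritParams total_input
#' @return the successor bit vector.
#' @export
deterministic_update <- function(net, state) {
  state <- check_bits(state, n_nodes(net))
  h <- as.vector(net$interactions %*% state) - net$thresholds
  ifelse(h > 0, 1L, ifelse(h < 0, 0L, state))
}

#' @rdname deterministic_update
#' @param n_steps number of synchronous updates to apply.
#' @return `deterministic_trajectory`: an `(n_steps + 1) x n` bit matrix
#'   whose first row is `state`.
#' @export
deterministic_trajectory <- function(net, state, n_steps) {
  state <- check_bits(state, n_nodes(net))
  out <- matrix(0L, n_steps + 1L, n_nodes(net))
  out[1L, ] <- state
  for (k in seq_len(n_steps)) {
    state <- deterministic_update(net, state)
    out[k + 1L, ] <- state
  }
  colnames(out) <- net$nodes
  out
}

#' Read and write networks in the plain-text edge-list dialect
#'
#' The file is UTF-8 text with `#` comments and the sections:
#' \describe{
#'   \item{`[nodes]`}{one node name per line, in index order;}
#'   \item{`[edges]`}{lines `source<TAB>target<TAB>sign` with sign `+1`/`-1`;}
#'   \item{`[thresholds]`}{optional lines `node<TAB>value` for nodes with a
#'     non-zero activation threshold;}
#'   \item{`[checkpoint]`}{optional single line naming the checkpoint node;}
#'   \item{`[g0]`}{optional single line of n space-separated bits (the
#'     resting state).}
#' }
#' `save_network()` followed by `load_network()` round-trips a network
#' exactly. Malformed lines, unknown node names, duplicate edges and signs
#' outside `{-1, +1}` are rejected with the offending line number.
#'
#' @param path file path.
#' @return `load_network`: a `regulatory_network`.
#' @export
load_network <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  section <- ""
  nodes <- character()
  edges <- list()
  thresholds <- list()
  checkpoint <- NULL
  g0 <- NULL
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    if (grepl("^\\[.*\\]$", txt)) {
      section <- sub("^\\[(.*)\\]$", "\\1", txt)
      if (!section %in% c("nodes", "edges", "thresholds", "checkpoint", "g0"))
        stop(sprintf("line %d: unknown section '[%s]'", ln, section))
      next
    }
    if (section == "nodes") {
      nodes <- c(nodes, txt)
    } else if (section == "edges") {
      f <- strsplit(txt, "\t", fixed = TRUE)[[1]]
      if (length(f) != 3L)
        stop(sprintf("line %d: edge lines must be 'source<TAB>target<TAB>sign'", ln))
      sgn <- suppressWarnings(as.integer(f[3]))
      if (is.na(sgn) || !sgn %in% c(-1L, 1L))
        stop(sprintf("line %d: edge sign must be +1 or -1", ln))
      edges[[length(edges) + 1L]] <- list(src = f[1], dst = f[2], sign = sgn, line = ln)
    } else if (section == "thresholds") {
      f <- strsplit(txt, "\t", fixed = TRUE)[[1]]
      if (length(f) != 2L)
        stop(sprintf("line %d: threshold lines must be 'node<TAB>value'", ln))
      thresholds[[length(thresholds) + 1L]] <- list(node = f[1], value = as.numeric(f[2]), line = ln)
    } else if (section == "checkpoint") {
      checkpoint <- txt
    } else if (section == "g0") {
      g0 <- as.integer(strsplit(txt, "[[:space:]]+")[[1]])
    } else {
      stop(sprintf("line %d: content outside any section", ln))
    }
  }
  if (length(nodes) == 0L) stop("no [nodes] section found")
  n <- length(nodes)
  a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (e in edges) {
    i <- match(e$dst, nodes); j <- match(e$src, nodes)
    if (is.na(i) || is.na(j))
      stop(sprintf("line %d: edge references unknown node '%s'",
                   e$line, if (is.na(j)) e$src else e$dst))
    if (a[i, j] != 0L)
      stop(sprintf("line %d: duplicate edge %s -> %s", e$line, e$src, e$dst))
    a[i, j] <- e$sign
  }
  th <- numeric(n)
  for (t in thresholds) {
    i <- match(t$node, nodes)
    if (is.na(i))
      stop(sprintf("line %d: threshold references unknown node '%s'", t$line, t$node))
    th[i] <- t$value
  }
  cp <- 1L
  if (!is.null(checkpoint)) {
    cp <- match(checkpoint, nodes)
    if (is.na(cp)) stop(sprintf("unknown checkpoint node '%s'", checkpoint))
  }
  regulatory_network(nodes, a, g0_state = g0, checkpoint = cp, thresholds = th)
}

#' @rdname load_network
#' @param net a `regulatory_network`.
#' @export
save_network <- function(net, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("[nodes]")
  writeLines(net$nodes, con)
  w("[edges]")
  idx <- which(net$interactions != 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]  # by source, then target
  for (k in seq_len(nrow(idx)))
    w("%s\t%s\t%+d", net$nodes[idx[k, 2L]], net$nodes[idx[k, 1L]],
      net$interactions[idx[k, 1L], idx[k, 2L]])
  if (any(net$thresholds != 0)) {
    w("[thresholds]")
    for (i in which(net$thresholds != 0))
      w("%s\t%s", net$nodes[i], format(net$thresholds[i]))
  }
  w("[checkpoint]")
  w("%s", net$nodes[net$checkpoint])
  if (!is.null(net$g0_state)) {
    w("[g0]")
    w("%s", paste(net$g0_state, collapse = " "))
  }
  invisible(path)
}

#' Native (biological) paths
#'
#' A native path is the ordered list of global states visited by the
#' biological cycle. The file format is one state per line as n
#' space-separated bits, with an optional trailing phase label.
#'
#' @param states a `k x n` bit matrix (one state per row) or list of bit
#'   vectors.
#' @param labels optional character vector of phase labels.
#' @return an object of class `native_path` with elements `states` (bit
#'   matrix), `labels`, and `indices` (canonical 0-based state indices).
#' @export
native_path <- function(states, labels = NULL) {
  if (is.list(states)) states <- do.call(rbind, states)
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  apply(states, 1L, check_bits)
  idx <- apply(states, 1L, encode_state)
  if (anyDuplicated(idx)) stop("native path states must be distinct")
  if (!is.null(labels) && length(labels) != nrow(states))
    stop("one label per state required")
  structure(list(states = states, labels = labels, indices = idx),
            class = "native_path")
}

#' @export
print.native_path <- function(x, ...) {
  cat(sprintf("native_path: %d states on %d nodes\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' @rdname native_path
#' @param path file path.
#' @export
load_native_path <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", raw))
  lines <- lines[nzchar(lines)]
  states <- list(); labels <- character()
  for (txt in lines) {
    f <- strsplit(txt, "[[:space:]]+")[[1]]
    isbit <- grepl("^[01]$", f)
    nb <- match(FALSE, isbit, nomatch = length(f) + 1L) - 1L
    if (nb < 1L) stop("native path line has no bits: ", txt)
    states[[length(states) + 1L]] <- as.integer(f[seq_len(nb)])
    labels <- c(labels, if (nb < length(f)) paste(f[-seq_len(nb)], collapse = " ") else NA_character_)
  }
  if (all(is.na(labels))) labels <- NULL
  native_path(states, labels)
}

#' @rdname native_path
#' @param np a `native_path`.
#' @export
save_native_path <- function(np, path) {
  lines <- apply(np$states, 1L, paste, collapse = " ")
  if (!is.null(np$labels))
    lines <- paste(lines, np$labels)
  writeLines(lines, path)
  invisible(path)
}

#' The fission yeast cell-cycle network fixture
#'
#' Loads the bundled ten-node fission yeast cell-cycle wiring (checkpoint
#' node CS plus nine gene/protein nodes, 27 signed edges including four
#' self-degradation loops) together with its ten-state biological path
#' START -> G1 -> G1/S -> G2 -> G2/M -> M -> G1/G0. The two activation
#' thresholds inherited from the underlying deterministic Boolean model
#' (Davidich & Bornholdt 2008, PLoS ONE 3:e1672) are set in the fixture
#' file; see the file header in `inst/extdata/` for edge-by-edge sign
#' provenance.
#'
#' @return a list with elements `network` (a `regulatory_network`) and
#'   `native_path` (a `native_path` of the 10 cycle states).
#' @examples
#' fy <- fission_yeast_fixture()
#' n_nodes(fy$network)       # 10
#' sum(fy$network$interactions != 0)  # 27
#' @export
fission_yeast_fixture <- function() {
  netfile <- system.file("extdata", "fission_yeast.net", package = "fluxscape",
                         mustWork = TRUE)
  pathfile <- system.file("extdata", "fission_yeast_native_path.txt",
                          package = "fluxscape", mustWork = TRUE)
  list(network = load_network(netfile), native_path = load_native_path(pathfile))
}

#' Ring-chain generator (oracle input for flux and dissipation tests)
#'
#' Builds the explicit row-stochastic transition matrix of a biased ring on
#' `n_states` abstract states: forward probability `p_forward`, backward
#' `p_backward`, remainder on the self-loop. With `p_forward == p_backward`
#' the chain is detailed balanced; a bias produces a single flux loop with
#' known flux `(p_forward - p_backward) / n_states` and entropy production
#' rate `(p_forward - p_backward) * log(p_forward / p_backward)`.
#'
#' @param n_states number of ring states (>= 2).
#' @param p_forward,p_backward step probabilities with
#'   `p_forward + p_backward <= 1`.
#' @return an `n_states x n_states` row-stochastic matrix.
#' @export
toy_ring <- function(n_states, p_forward, p_backward) {
  if (n_states < 2L) stop("ring needs at least 2 states")
  if (p_forward < 0 || p_backward < 0 || p_forward + p_backward > 1)
    stop("need p_forward, p_backward >= 0 and p_forward + p_backward <= 1")
  T <- diag(1 - p_forward - p_backward, n_states)
  fwd <- cbind(seq_len(n_states), c(seq_len(n_states)[-1L], 1L))
  T[fwd] <- T[fwd] + p_forward
  T[fwd[, 2:1, drop = FALSE]] <- T[fwd[, 2:1, drop = FALSE]] + p_backward
  T
}
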