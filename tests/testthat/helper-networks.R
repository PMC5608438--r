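# Shared toy builders, oracles and a memoised fixture solution.

# single isolated node (no inputs): everything runs on the c-rule
toy_one_node <- function() {
  regulatory_network("A", matrix(0L, 1, 1))
}

# two independent nodes: A has no inputs, B has no inputs
toy_two_independent <- function() {
  regulatory_network(c("A", "B"), matrix(0L, 2, 2))
}

# small mutual-repression pair with self-degradation on A
toy_repressilator2 <- function() {
  a <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  a[1, 2] <- -1L; a[2, 1] <- -1L; a[1, 1] <- -1L
  regulatory_network(c("A", "B"), a)
}

# random signed network on n nodes with given edge density, plus a g0 state
random_network <- function(n, density = 0.4) {
  a <- matrix(sample(c(-1L, 0L, 1L), n * n, replace = TRUE,
                     prob = c(density / 2, 1 - density, density / 2)), n, n)
  regulatory_network(paste0("n", seq_len(n)), a,
                     g0_state = sample(0:1, n, replace = TRUE))
}

# random dense irreducible row-stochastic matrix on n abstract states
random_chain <- function(n) {
  T <- matrix(runif(n * n) + 0.05, n, n)
  T / rowSums(T)
}

# 5-state "figure eight": two directed 3-cycles 0->1->2->0 and 0->3->4->0
# sharing state 0, with stay-put remainder. Loop fluxes have a closed form:
# at stationarity both cycles carry flux P0*a and P0*b respectively.
toy_figure_eight <- function(a = 0.3, b = 0.15) {
  stopifnot(a + b <= 1)
  T <- diag(5)
  T[1, 1] <- 1 - a - b; T[1, 2] <- a; T[1, 4] <- b
  T[2, 2] <- 0;         T[2, 3] <- 1
  T[3, 3] <- 0;         T[3, 1] <- 1
  T[4, 4] <- 0;         T[4, 5] <- 1
  T[5, 5] <- 0;         T[5, 1] <- 1
  T
}

# memoised fixture solution at the canonical parameters
.fixture_cache <- new.env(parent = emptyenv())
fixture_solution <- function() {
  if (is.null(.fixture_cache$sol)) {
    fy <- fission_yeast_fixture()
    params <- model_parameters(mu = 5, c = 0.001, gamma = 0.6)
    T <- build_transition_matrix(fy$network, params)
    P <- solve_steady_state(T)
    .fixture_cache$sol <- list(net = fy$network, path = fy$native_path,
                               params = params, T = T, P = P)
  }
  .fixture_cache$sol
}

# memoised single-edge-deletion TES ranking (the 27-solve sweep)
fixture_ranking <- function() {
  if (is.null(.fixture_cache$rank)) {
    sol <- fixture_solution()
    t0 <- Sys.time()
    rk <- rank_edges_TES(sol$net, sol$params, sol$path)
    attr(rk, "elapsed_secs") <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .fixture_cache$rank <- rk
  }
  .fixture_cache$rank
}
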