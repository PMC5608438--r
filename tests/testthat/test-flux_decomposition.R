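test_that("steady-state flux is antisymmetric and vanishes at detailed balance", {
  Tb <- toy_ring(4, 0.25, 0.25)
  Pb <- solve_steady_state(Tb)
  expect_lt(max(abs(steady_state_flux(Tb, Pb))), 1e-14)

  T <- toy_ring(3, 0.2, 0.1)
  P <- solve_steady_state(T)
  F <- steady_state_flux(T, P)
  expect_equal(F, -t(F))
  expect_lt(max(abs(rowSums(F))), 1e-14)
  # each directed ring edge carries (p_f - p_b)/3 net flux
  expect_equal(F[2, 1], (0.2 - 0.1) / 3, tolerance = 1e-12)
  expect_error(steady_state_flux(T, c(0.8, 0.1, 0.1)), "stationary")
})

test_that("C/D decomposition identities hold on random chains", {
  set.seed(5)
  for (n in c(4, 16, 64)) {
    T <- random_chain(n)
    P <- solve_steady_state(T)
    cd <- decompose_CD(T, P)
    M <- T; diag(M) <- diag(T) - 1
    expect_lt(max(abs(cd$C + cd$D - M)), 1e-12)               # M = C + D
    expect_lt(max(abs(as.vector(t(cd$C) %*% P))), 1e-10)      # C' P = 0
    expect_lt(max(abs(as.vector(t(cd$D) %*% P))), 1e-10)      # D' P = 0
    DB <- cd$D * P                                            # D_ij P_i
    expect_lt(max(abs(DB - t(DB))), 1e-14)                    # detailed balance
    CB <- cd$C * P
    diag(CB) <- 0
    expect_lt(max(pmin(CB, t(CB))), 1e-18)                    # one-way
  }
})

test_that("C and D specialize correctly in the limits", {
  # detailed-balanced chain: C has no off-diagonal part, D carries M
  Tb <- toy_ring(4, 0.2, 0.2)
  Pb <- solve_steady_state(Tb)
  cd <- decompose_CD(Tb, Pb)
  expect_lt(max(abs(cd$C)), 1e-13)
  # deterministic ring: D empty, C carries everything
  Td <- toy_ring(3, 1, 0)
  Pd <- solve_steady_state(Td)
  cd2 <- decompose_CD(Td, Pd)
  expect_lt(max(abs(cd2$D)), 1e-13)
  offC <- cd2$C; diag(offC) <- 0
  offM <- Td; diag(offM) <- 0
  expect_equal(offC, offM)
})

test_that("loop peeling recovers elementary cycles", {
  # deterministic 3-ring: one loop of flux 1/3
  Td <- toy_ring(3, 1, 0)
  J <- flux_matrix(Td, solve_steady_state(Td))
  loops <- extract_loops(J)
  expect_equal(length(loops$flux), 1)
  expect_equal(loops$flux, 1 / 3, tolerance = 1e-12)
  expect_equal(sort(loops$states[[1]]), c(0, 1, 2))

  # empty flux
  expect_equal(length(extract_loops(matrix(0, 3, 3))$flux), 0)

  # two disjoint 2-cycles with fluxes a and b (superposition)
  J2 <- matrix(0, 4, 4)
  J2[1, 2] <- J2[2, 1] <- 0.4
  J2[3, 4] <- J2[4, 3] <- 0.1
  loops2 <- extract_loops(J2)
  expect_equal(sort(loops2$flux), c(0.1, 0.4))
  expect_equal(loops_to_matrix(loops2, 4), J2)

  # unbalanced input is rejected
  Jbad <- matrix(0, 3, 3); Jbad[1, 2] <- 1
  expect_error(extract_loops(Jbad), "conserv")
})

test_that("peeling reconstructs J edge-wise on random chains", {
  set.seed(9)
  for (n in c(8, 32)) {
    T <- random_chain(n)
    P <- solve_steady_state(T)
    J <- flux_matrix(T, P)
    expect_lt(max(abs(rowSums(J) - colSums(J))), 1e-12)   # conservation
    loops <- extract_loops(J)
    expect_lt(max(abs(loops_to_matrix(loops, n) - J)), 1e-10)
    expect_true(all(loops$flux > 0))
    # no repeated interior state within any loop
    expect_true(all(vapply(loops$states,
                           function(s) !anyDuplicated(s), logical(1))))
  }
})

test_that("flux landscape normalizes loops and finds the native cycle", {
  loops <- structure(list(states = list(c(0L, 1L, 2L), c(5L, 6L)),
                          flux = c(0.3, 0.1), total_flux = 0.4),
                     class = "flux_loops")
  np <- native_path(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))  # indices 0,1,2
  fl <- flux_landscape(loops, np)
  expect_equal(fl$P_flux, c(0.75, 0.25))
  expect_equal(fl$U_flux, -log(c(0.75, 0.25)))
  expect_equal(fl$native_loops, 1L)
  # single loop: P_flux 1, U_flux 0
  one <- structure(list(states = list(c(0L, 1L)), flux = 0.2, total_flux = 0.2),
                   class = "flux_loops")
  fl1 <- flux_landscape(one)
  expect_equal(fl1$P_flux, 1)
  expect_equal(fl1$U_flux, 0)
  # rotation matters but direction is preserved
  loops_rev <- structure(list(states = list(c(2L, 1L, 0L)), flux = 0.3,
                              total_flux = 0.3), class = "flux_loops")
  expect_length(flux_landscape(loops_rev, np)$native_loops, 0)
  # detailed-balance limit: empty landscape is an error
  none <- structure(list(states = list(), flux = numeric(), total_flux = 0),
                    class = "flux_loops")
  expect_error(flux_landscape(none), "detailed balanced")
})

test_that("trajectory loop statistics excise loops left to right", {
  # A,B,A -> one loop (A,B)
  st <- trajectory_loop_statistics(c(0L, 1L, 0L))
  expect_equal(nrow(st), 1)
  expect_equal(st$loop, "0-1")
  expect_equal(st$count, 1L)
  # no revisits -> empty table
  expect_equal(nrow(trajectory_loop_statistics(c(3L, 1L, 4L, 2L))), 0)
  # self-transitions are not loops
  expect_equal(nrow(trajectory_loop_statistics(c(2L, 2L, 2L))), 0)
  # nested loops: 0,1,2,1,3,0 gives (1,2) then (0,1,3)
  st2 <- trajectory_loop_statistics(c(0L, 1L, 2L, 1L, 3L, 0L))
  expect_setequal(st2$loop, c("1-2", "0-1-3"))
})

test_that("empirical loop fractions converge to the matrix decomposition", {
  # figure-eight chain: loops (0,1,2) and (0,3,4) with flux ratio a : b
  a <- 0.3; b <- 0.15
  T <- toy_figure_eight(a, b)
  P <- solve_steady_state(T)
  loops <- extract_loops(flux_matrix(T, P))
  expect_equal(length(loops$flux), 2)
  fl <- flux_landscape(loops)
  expect_equal(sort(fl$P_flux), sort(c(a, b) / (a + b)), tolerance = 1e-10)

  traj <- simulate_markov(T, 2e5, seed = 101)
  st <- trajectory_loop_statistics(traj)
  stopifnot(nrow(st) == 2)
  pA <- st$p_flux[st$loop == "0-1-2"]
  n <- sum(st$count)
  se <- sqrt(pA * (1 - pA) / n)
  expect_lt(abs(pA - a / (a + b)), 3 * se + 1e-6)
})

test_that("fixture flux: conservation holds and the native loop dominates", {
  sol <- fixture_solution()
  J <- flux_matrix(sol$T, sol$P)
  expect_lt(max(abs(rowSums(J) - colSums(J))), 1e-12)
  loops <- extract_loops(J)
  expect_lt(max(abs(loops_to_matrix(loops, 1024) - J)), 1e-10)
  fl <- flux_landscape(loops, sol$path)
  expect_length(fl$native_loops, 1)
  # the native biological loop carries the minimal loop potential
  expect_equal(which.min(fl$U_flux), fl$native_loops)
  # and the trajectory route finds the same dominant loop
  params <- sol$params
  traj <- simulate_trajectory(sol$net, params, 2e4, seed = 17)
  st <- trajectory_loop_statistics(traj)
  expect_equal(st$loop[1], loop_key(loops$states[[fl$native_loops]]))
  # its empirical completion rate per step matches its peeled flux
  rate <- st$count[1] / 2e4
  se <- sqrt(st$count[1]) / 2e4
  expect_lt(abs(rate - loops$flux[fl$native_loops]), 4 * se)
})
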