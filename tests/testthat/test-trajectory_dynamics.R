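test_that("trajectories are seed-reproducible and respect the kernel", {
  fy <- fission_yeast_fixture()
  p <- model_parameters(5, 0.001, 0.6)
  t1 <- simulate_trajectory(fy$network, p, 500, seed = 42)
  t2 <- simulate_trajectory(fy$network, p, 500, seed = 42)
  expect_identical(t1$states, t2$states)
  expect_length(t1$states, 501)
  t3 <- simulate_trajectory(fy$network, p, 500, seed = 43)
  expect_false(identical(t1$states, t3$states))
})

test_that("the saturated limit cycles deterministically through the biological path", {
  fy <- fission_yeast_fixture()
  p <- model_parameters(mu = 50, c = 0, gamma = 1)
  traj <- simulate_trajectory(fy$network, p, 40, seed = 1,
                              initial_state = fy$native_path$states[1, ])
  expect_equal(traj$states[1:10], fy$native_path$indices)
  # gamma = 1 restarts the cycle immediately: period 10
  expect_equal(traj$states[11:20], fy$native_path$indices)
  expect_equal(traj$states[21:30], fy$native_path$indices)
})

test_that("empirical visit frequencies match the stationary law (ergodicity)", {
  T <- toy_figure_eight(0.3, 0.15)
  P <- solve_steady_state(T)
  traj <- simulate_markov(T, 2e5, seed = 7)
  emp <- tabulate(traj + 1L, nbins = 5) / length(traj)
  se <- sqrt(P * (1 - P) / length(traj))
  expect_true(all(abs(emp - P) < 4 * se + 1e-4))
})

test_that("autocorrelation has the expected shapes", {
  set.seed(21)
  # white noise: 1 at lag 0, near zero elsewhere
  w <- rnorm(4000)
  ac <- autocorrelation(w, 20)
  expect_equal(ac[1], 1)
  expect_lt(max(abs(ac[-1])), 0.1)
  # deterministic period 10: autocorrelation 1 at lag 10
  s <- rep(c(1, 3, 0, 2, 5, 4, 2, 0, 1, 7), 40)
  acs <- autocorrelation(s, 12)
  expect_equal(acs[11], 1, tolerance = 0.05)
  # sine: cosine-shaped autocorrelation
  x <- sin(2 * pi * (1:2000) / 50)
  acx <- autocorrelation(x, 100)
  expect_equal(acx[51], cos(2 * pi * 50 / 50), tolerance = 0.1)
  expect_equal(acx[26], cos(2 * pi * 25 / 50), tolerance = 0.1)
  expect_error(autocorrelation(rep(2, 100), 5), "constant")
  expect_error(autocorrelation(1:10, 50), "max_lag")
})

test_that("power spectrum finds pure tones and is Parseval-consistent", {
  n <- 1024
  x <- sin(2 * pi * 32 * (1:n) / n)          # frequency 32/1024
  sp <- power_spectrum(x)
  expect_equal(sp$dominant_frequency, 32 / n, tolerance = 1 / n)
  # Parseval: total one-sided power equals the biased variance
  set.seed(8)
  y <- rnorm(n)
  spy <- power_spectrum(y)
  expect_equal(sum(spy$power), mean((y - mean(y))^2), tolerance = 1e-8)
  # white noise is flat: no bin towers over the median
  expect_lt(spy$dominant_power, 30 * median(spy$power[-1]))
  expect_error(power_spectrum(rep(1, 128)), "constant")
  expect_error(power_spectrum(rnorm(32)), "too short")
})

test_that("spectrum equals the Fourier transform of the circular autocorrelation", {
  set.seed(30)
  x <- rnorm(256)
  xc <- x - mean(x)
  n <- length(xc)
  # independent route: circular (wrap-around) autocovariance, then DFT
  r <- vapply(0:(n - 1), function(k)
    sum(xc * xc[((seq_len(n) - 1 + k) %% n) + 1]) / n, numeric(1))
  spec_wk <- Re(fft(r)) / n
  sp <- power_spectrum(x)
  half <- floor(n / 2)
  folded <- spec_wk[1:(half + 1)]
  folded[2:half] <- 2 * folded[2:half]
  expect_equal(sp$power, folded, tolerance = 1e-10)
})

test_that("oscillation emerges with the checkpoint excitation", {
  fy <- fission_yeast_fixture()
  band <- function(s) sum(s$power[s$frequencies >= 0.05 &
                                  s$frequencies <= 0.2]) / sum(s$power[-1])
  # no pumping: rare basal excursions give a random-telegraph spectrum
  # whose power piles up next to DC -- no oscillatory peak
  p0 <- model_parameters(5, 0.001, 0)
  t0 <- simulate_trajectory(fy$network, p0, 2^13, seed = 5)
  s0 <- trajectory_spectrum(t0, fy$network)
  expect_lt(s0$dominant_frequency, 0.01)
  # gamma = 0.6: the dominant peak sits at the ~10-step cycle frequency
  p1 <- model_parameters(5, 0.001, 0.6)
  t1 <- simulate_trajectory(fy$network, p1, 2^13, seed = 5)
  s1 <- trajectory_spectrum(t1, fy$network)
  expect_gt(s1$dominant_power, 30 * median(s1$power[-1]))
  expect_gt(s1$dominant_frequency, 0.05)
  expect_lt(s1$dominant_frequency, 0.2)
  # and the oscillation band carries far more of the variance than at gamma 0
  expect_gt(band(s1), 5 * band(s0))
})

test_that("parameter sweep table is deterministic and correlates flux with speed", {
  fy <- fission_yeast_fixture()
  p <- model_parameters(5, 0.001, 0.6)
  grid <- c(0.05, 0.30)
  tab <- dominant_frequency_vs_parameter(fy$network, p, "gamma", grid,
                                         fy$native_path, n_steps = 2^13,
                                         n_replicates = 2, seeds = 77)
  expect_equal(nrow(tab), 2)
  tab2 <- dominant_frequency_vs_parameter(fy$network, p, "gamma", grid,
                                          fy$native_path, n_steps = 2^13,
                                          n_replicates = 2, seeds = 77)
  expect_identical(tab, tab2)
  expect_true(all(diff(tab$native_flux) > 0))
  single <- dominant_frequency_vs_parameter(fy$network, p, "mu", 5,
                                            fy$native_path, n_steps = 2^12,
                                            n_replicates = 1, seeds = 3)
  expect_equal(nrow(single), 1)
})
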