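test_that("zero-temperature dynamics stay at a minimum", {
  V <- dw()
  p <- langevin_params(D = 1, kT = 0, dt = 1e-3)
  tr <- simulate_langevin(V, p, 500, initial = 1, mobility = 1)
  expect_equal(tr$x, rep(1, length(tr$x)))
  # and relax downhill to the nearest minimum from elsewhere
  tr2 <- simulate_langevin(V, p, 5000, initial = 0.8, mobility = 1)
  expect_equal(tail(tr2$x, 1), 1, tolerance = 1e-4)
})

test_that("free diffusion has MSD = 2 D t within 5%", {
  p <- langevin_params(D = 0.7, kT = 1, dt = 1e-3, seed = 3)
  tr <- simulate_langevin(flat_potential(), p, 1e6, 0)
  m <- msd(tr$x, lags = c(10, 30, 100), dt = p$dt)
  expect_equal(m$msd / (2 * 0.7 * m$lag_time), rep(1, 3), tolerance = 0.05)
})

test_that("the long-run histogram matches the Boltzmann density (KL < 0.01)", {
  V <- triple_well(c(0, 0.4, 1.8), c(2, 3))
  p <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = 7)
  tr <- simulate_langevin(V, p, 1e6, initial = 0.4)
  bd <- boltzmann_density(V, 1)
  edges <- seq(min(bd$x), max(bd$x), by = 0.02)
  h <- hist(tr$x, breaks = c(-Inf, edges, Inf), plot = FALSE)$counts
  h <- h[-c(1, length(h))]
  ph <- h / sum(h)
  dens <- stats::approxfun(bd$x, bd$density)
  pa <- vapply(seq_len(length(edges) - 1), function(i)
    stats::integrate(dens, edges[i], edges[i + 1])$value, numeric(1))
  pa <- pa / sum(pa)
  keep <- pa > 1e-12 & ph > 0
  kl <- sum(ph[keep] * log(ph[keep] / pa[keep]))
  expect_lt(kl, 0.01)
})

test_that("identical seeds give identical trajectories", {
  V <- tw()
  p <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = 42)
  expect_identical(simulate_langevin(V, p, 1e4, 0.4)$x,
                   simulate_langevin(V, p, 1e4, 0.4)$x)
})

test_that("too-large time steps and out-of-domain starts are rejected", {
  V <- tw()  # narrowest well width 0.2 -> step sd must be < 0.02
  expect_error(simulate_langevin(V, langevin_params(dt = 1e-3), 10, 0),
               "time step too large")
  expect_error(simulate_langevin(V, langevin_params(dt = 1e-4), 10, 100),
               "domain")
})

test_that("a diverging trajectory aborts with a diagnostic", {
  # nearly-free confinement and high temperature let the walker escape
  V <- double_well(c(0, 1), 0.5, k_conf = 1e-6)
  p <- langevin_params(D = 1, kT = 50, dt = 1e-3, seed = 8)
  expect_error(simulate_langevin(V, p, 1e6, 0.5), "diverged")
})

test_that("brute-force rates on a symmetric double well are symmetric and
           satisfy detailed balance", {
  V <- dw(4)
  p <- langevin_params(D = 1, kT = 1, dt = 5e-4, seed = 11)
  bf <- brute_force_rates(V, p, 1e7, dw_basins(), thin = 10L)
  expect_false(bf$unreliable)
  expect_gt(bf$n_ab, 50)
  # forward/backward symmetry within 3 bootstrap SE
  expect_lt(abs(bf$k_ab - bf$k_ba), 3 * sqrt(bf$se_ab^2 + bf$se_ba^2))
  # detailed balance with interval occupancies from the same trajectory
  lhs <- bf$k_ab * bf$occ_a
  rhs <- bf$k_ba * bf$occ_b
  se <- sqrt((bf$se_ab * bf$occ_a)^2 + (bf$se_ba * bf$occ_b)^2)
  expect_lt(abs(lhs - rhs), 3 * se)
})

test_that("raising the barrier by 1 kT slows the rate by about a factor e", {
  p <- langevin_params(D = 1, kT = 1, dt = 5e-4, seed = 12)
  b4 <- brute_force_rates(dw(4), p, 1.2e7, dw_basins(), thin = 10L)
  p2 <- langevin_params(D = 1, kT = 1, dt = 5e-4, seed = 13)
  b5 <- brute_force_rates(dw(5), p2, 1.2e7, dw_basins(), thin = 10L)
  ratio <- b4$k_ab / b5$k_ab
  # Kramers prefactors are equal by construction; allow stochastic error
  expect_gt(ratio, exp(1) * 0.8)
  expect_lt(ratio, exp(1) * 1.25)
})

test_that("insufficient transitions are flagged unreliable", {
  V <- dw(8)
  p <- langevin_params(D = 1, kT = 1, dt = 5e-4, seed = 14)
  expect_warning(bf <- brute_force_rates(V, p, 2e5, dw_basins(), thin = 10L),
                 "unreliable")
  expect_true(bf$unreliable)
})

test_that("transition_stats counts transitions and durations correctly on a
           hand-built series", {
  # A(0.0) .. climb .. B(1.0) .. back to A; one TP each way
  x <- c(0, 0.1, 0.3, 0.5, 0.9, 1.0, 1.0, 0.6, 0.4, 0.1, 0)
  basins <- basin_spec(a = c(-0.2, 0.2), b = c(0.85, 1.2))
  ts <- transition_stats(x, dt = 1, basins)
  expect_equal(nrow(ts$events), 2)
  expect_equal(ts$events$from, c(1, 2))
  expect_equal(ts$events$to, c(2, 1))
  expect_equal(ts$events$duration, c(2, 2))
  expect_equal(sum(ts$tp_frame), 4)
  expect_equal(harvest_tps(x, 1, basins, "ab")$duration, 2)
})
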