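test_that("a single unbiased window reduces to -kT log(histogram)", {
  p <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = 21)
  tr <- simulate_langevin(triple_well(c(0, 0.4, 1.8), c(2, 3)), p, 2e5,
                          0.4, thin = 10)
  bins <- bin_spec(-0.3, 2.2, 0.05)
  fit <- wham(list(umbrella_window(0, 0, tr$x)), bins)
  h <- helixtps:::tabulate_bins(tr$x, bins)
  Fh <- -log(h / sum(h) / bins$width)
  keep <- h > 0
  expect_equal(fit$pmf$F[keep] - min(fit$pmf$F[keep]),
               Fh[keep] - min(Fh[keep]), tolerance = 1e-9)
})

test_that("WHAM recovers a known triple well and is self-consistent", {
  V <- tw(4, 6)
  centers <- seq(-0.1, 2.0, by = 0.1)
  wins <- lapply(seq_along(centers), function(i) {
    p <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = 100 + i)
    tr <- simulate_langevin(V, p, 1.5e5, initial = centers[i], thin = 10,
                            bias = list(center = centers[i], k = 150))
    umbrella_window(centers[i], 150, tr$x, id = i)
  })
  bins <- bin_spec(-0.3, 2.2, 0.02)
  fit <- wham(wins, bins)
  expect_lt(fit$residual, 1e-7)              # converged to tolerance
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_equal(sum(fit$pmf$density) * bins$width, 1, tolerance = 1e-9)
  pm <- fit$pmf
  Vt <- potential_value(V, pm$bins[[1]]$mids)
  ok <- is.finite(pm$F) & pm$n_eff >= 100
  expect_gt(sum(ok), 50)
  d <- pm$F[ok] - Vt[ok]
  d <- d - weighted.mean(d, pm$n_eff[ok])
  expect_lt(max(abs(d)), 0.3)
  # barriers located within one bin width of the analytic maxima
  bar <- locate_barriers(pm, min_n_eff = 100)
  expect_equal(nrow(bar), 2)
  expect_equal(bar$position, c(0.2, 1.1), tolerance = 0.021)
  # projection onto the bias coordinate reproduces the WHAM profile
  pj <- project_pmf(fit$weights, fit$cv, bins)
  expect_equal(pj$density, pm$density, tolerance = 1e-12)
})

test_that("non-overlapping windows raise an error naming the gap", {
  p <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = 1)
  V <- dw(2)
  w1 <- umbrella_window(0, 200, simulate_langevin(
    V, p, 2e4, 0, bias = list(center = 0, k = 200), thin = 10)$x)
  p2 <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = 2)
  w2 <- umbrella_window(1, 200, simulate_langevin(
    V, p2, 2e4, 1, bias = list(center = 1, k = 200), thin = 10)$x)
  expect_error(wham(list(w1, w2), bin_spec(-0.3, 1.3, 0.02)),
               "non-overlapping")
})

test_that("projection handles constant and 2D coordinates, and validates", {
  w <- rep(1 / 100, 100)
  pj <- project_pmf(w, rep(0.5, 100), bin_spec(0, 1, 0.1))
  expect_equal(sum(pj$density > 0), 1)
  expect_equal(pj$F[pj$density > 0], 0)
  expect_error(project_pmf(w, runif(50), bin_spec(0, 1, 0.1)),
               "different lengths")
  set.seed(5)
  p2 <- project_pmf(w, runif(100), bin_spec(0, 1, 0.25),
                    runif(100), bin_spec(0, 1, 0.25))
  expect_equal(p2$dim, 2L)
  expect_equal(sum(p2$density) * 0.25^2, 1, tolerance = 1e-9)
})

test_that("locate_barriers handles monotone, symmetric and noisy profiles", {
  bins <- bin_spec(0, 1, 0.05)
  mono <- project_pmf(exp(-5 * bins$mids), bins$mids, bins)
  expect_equal(nrow(locate_barriers(mono)), 0)
  # symmetric double well: single barrier at the midpoint (the density is
  # integrated on a fine subgrid so binning artefacts stay below the
  # height filter)
  V <- double_well(c(-1, 1), 3)
  x <- seq(-1.2, 1.2, by = 0.0005)
  dens <- exp(-potential_value(V, x))
  pm <- project_pmf(dens, x, bin_spec(-1.25, 1.25, 0.05))
  bar <- locate_barriers(pm)
  bar <- bar[bar$height > 0.5, ]
  expect_equal(nrow(bar), 1)
  expect_equal(bar$position, 0, tolerance = 0.026)
  expect_equal(bar$height, 3, tolerance = 0.1)
  expect_error(locate_barriers(project_pmf(1, 0.5, bin_spec(0, 1, 0.5))),
               "3 bins")
})

test_that("equilibrium constants integrate the PMF correctly", {
  # symmetric double well: K = 1 by symmetry
  V <- double_well(c(-1, 1), 3)
  x <- seq(-1.6, 1.6, by = 0.0005)
  pm <- project_pmf(exp(-potential_value(V, x)), x, bin_spec(-1.6, 1.6, 0.02))
  K <- equilibrium_constant(pm, 0)
  expect_equal(K$K_eq, 1, tolerance = 1e-3)
  expect_equal(K$p_bound + K$p_unbound, 1)
  # two square wells of equal width and depth difference dF: K = exp(dF)
  xs <- seq(0.005, 1.995, by = 0.01)
  dens <- ifelse(xs < 1, exp(1.3), 1)
  K2 <- equilibrium_constant(project_pmf(dens, xs, bin_spec(0, 2, 0.01)), 1)
  expect_equal(K2$K_eq, exp(1.3), tolerance = 1e-9)
  expect_error(equilibrium_constant(pm, 99), "interior")
})

test_that("triple-well populations from the PMF match trajectory occupancy", {
  V <- triple_well(c(0, 0.4, 1.8), c(2.5, 3.5))
  p <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = 77)
  tr <- simulate_langevin(V, p, 6e6, 0.4, thin = 10)
  # PMF from the analytic density; divider at the second barrier (1.1)
  bd <- boltzmann_density(V)
  pm <- project_pmf(bd$density, bd$x, bin_spec(min(bd$x), max(bd$x), 0.02))
  K <- equilibrium_constant(pm, 1.1)
  occ <- mean(tr$x < 1.1) / mean(tr$x >= 1.1)
  # agreement within the sampling error of the trajectory occupancy
  expect_equal(K$K_eq / occ, 1, tolerance = 0.2)
})

test_that("scan_mu finds an interior optimum when the angle separates the
           states and reduces to the D_RMS barrier at mu = 0", {
  # two states overlapping in drms but separated in theta
  set.seed(9)
  n <- 4000
  state <- rep(c(0, 1), each = n / 2)
  drms <- ifelse(state == 0, rnorm(n / 2, 0.35, 0.10),
                 rnorm(n / 2, 0.65, 0.10))
  theta <- ifelse(state == 0, rnorm(n / 2, -1.2, 0.35),
                  rnorm(n / 2, 1.2, 0.35))
  w <- rep(1 / n, n)
  grid <- c(0, 0.1, 0.2, 0.3, 0.5, 0.8)
  sc <- scan_mu(w, drms, theta, grid, bin_width = 0.05)
  expect_true(sc$mu_opt > 0 && sc$mu_opt < 0.8)   # interior maximizer
  ih <- sc$table$barrier
  im <- which.max(ih)
  expect_true(all(diff(ih[seq_len(im)]) >= 0))    # rises then falls
  expect_true(all(diff(ih[im:length(ih)]) <= 0))
  # mu = 0 column equals the barrier of the pure drms profile
  pm0 <- project_pmf(w, drms, bin_spec(min(drms), max(drms), 0.05))
  b0 <- locate_barriers(pm0)
  expect_equal(sc$table$barrier[1], max(b0$height), tolerance = 1e-9)
  # single-value grid returns that value
  expect_equal(scan_mu(w, drms, theta, 0.25, bin_width = 0.05)$mu_opt, 0.25)
})

test_that("pooled independent window sets agree within bootstrap error", {
  V <- tw(3, 4)
  centers <- seq(-0.1, 2.0, by = 0.15)
  mkset <- function(off) lapply(seq_along(centers), function(i) {
    p <- langevin_params(D = 1, kT = 1, dt = 1e-4, seed = off + i)
    tr <- simulate_langevin(V, p, 8e4, initial = centers[i], thin = 10,
                            bias = list(center = centers[i], k = 120))
    umbrella_window(centers[i], 120, tr$x, id = paste0(off, "_", i))
  })
  s1 <- mkset(1000); s2 <- mkset(2000)
  bins <- bin_spec(-0.3, 2.2, 0.05)
  f1 <- wham(s1, bins); f2 <- wham(s2, bins)
  bs1 <- wham_bootstrap(s1, bins, n_boot = 25)
  bs2 <- wham_bootstrap(s2, bins, n_boot = 25)
  ok <- is.finite(f1$pmf$F) & is.finite(f2$pmf$F) &
    f1$pmf$n_eff > 100 & f2$pmf$n_eff > 100
  d <- (f1$pmf$F - f2$pmf$F)[ok]
  d <- d - mean(d)
  se <- sqrt(bs1$se^2 + bs2$se^2)[ok]
  expect_lt(max(abs(d) / pmax(se, 0.02)), 5)
  # and the pooled fit lies between within the same errors
  fp <- wham(c(s1, s2), bins)
  dp <- (fp$pmf$F - f1$pmf$F)[ok]
  expect_lt(max(abs(dp - mean(dp)) / pmax(se, 0.02)), 5)
})
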