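test_that("the model validates its native pairs and builds C-terminal
           weights", {
  m <- toy_dimer_model()
  expect_equal(nrow(m$native_pairs), 6)
  expect_true(all(m$native_pairs[, 2] == m$native_pairs[, 1] + 1))
  expect_equal(m$g, (1:10 / 10)^6)
  expect_error(toy_dimer_model(native_pairs = cbind(1, 99)))
  expect_error(toy_dimer_model(native_pairs = rbind(c(1, 2), c(1, 2))),
               "duplicate")
  # amplitudes: nonspecific outer product; native bonus kept separate
  expect_equal(m$amp[3, 4], m$eps_nonspecific * m$g[3] * m$g[4])
  expect_equal(m$amp_nat[3, 4], m$eps_native)
  expect_equal(m$amp_nat[4, 3], 0)
})

test_that("analytic generalized forces match numerical differentiation", {
  m <- toy_dimer_model()
  par <- helixtps:::dimer_cpp_par(m, langevin_params(dt = 5e-5))
  set.seed(61)
  for (k in 1:4) {
    st <- c(runif(2, -1, 1), runif(1, -pi, pi), runif(1, -0.4, 0.4),
            runif(2, -1, 1) + c(0, 0.45), runif(1, -pi, pi),
            runif(1, -0.4, 0.4))
    g <- helixtps:::dimer_grad_cpp(par, st)
    gn <- vapply(1:8, function(c) {
      h <- 1e-6; sp <- st; sm <- st
      sp[c] <- sp[c] + h; sm[c] <- sm[c] - h
      (helixtps:::dimer_energy_cpp(par, sp, 0, 0) -
         helixtps:::dimer_energy_cpp(par, sm, 0, 0)) / (2 * h)
    }, numeric(1))
    expect_equal(g, gn, tolerance = 1e-5)
  }
})

test_that("native geometry: D_RMS is zero and every native pair is in
           contact", {
  m <- toy_dimer_model()
  nat <- dimer_native_conformation(m)
  ns <- dimer_native_set(m)
  expect_equal(drms(nat, ns), 0)
  expect_equal(nrow(ns), nrow(m$native_pairs))
  expect_equal(ns$r0, rep(m$r_contact, nrow(ns)), tolerance = 1e-12)
  cm <- contact_map(nat, 0.45)
  for (r in seq_len(nrow(m$native_pairs)))
    expect_true(cm[as.character(m$native_pairs[r, 1]),
                   as.character(m$native_pairs[r, 2])])
  # the intermediate (in-register dock) forms no native contacts
  im <- dimer_conformation(m, dimer_intermediate_state(m))
  cmi <- contact_map(im, 0.45)
  for (r in seq_len(nrow(m$native_pairs)))
    expect_false(cmi[as.character(m$native_pairs[r, 1]),
                     as.character(m$native_pairs[r, 2])])
})

test_that("identical seeds give bit-identical trajectories", {
  m <- toy_dimer_model()
  p <- langevin_params(dt = 5e-5, seed = 62)
  t1 <- simulate_toy_dimer(m, p, 3000, thin = 10)
  t2 <- simulate_toy_dimer(m, p, 3000, thin = 10)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$drms, t2$drms)
})

test_that("C++ and conformation-based CV paths agree frame by frame", {
  m <- toy_dimer_model()
  p <- langevin_params(dt = 5e-5, seed = 63)
  tr <- simulate_toy_dimer(m, p, 2000, initial = "native", thin = 100)
  ns <- dimer_native_set(m)
  anch <- dimer_anchors(m)
  for (f in seq_len(nrow(tr$states))) {
    conf <- dimer_conformation(m, tr$states[f, ])
    expect_equal(drms(conf, ns), tr$drms[f], tolerance = 1e-12)
    expect_equal(crossing_angle(conf, anch), tr$theta[f], tolerance = 1e-12)
  }
})

test_that("without attraction the rods diffuse freely and contacts are
           short-lived", {
  m <- toy_dimer_model(eps_native = 0, eps_nonspecific = 0)
  p <- langevin_params(dt = 5e-5, seed = 64)
  tr <- simulate_toy_dimer(m, p, 1e6, initial = "native", thin = 2)
  # the rods drift apart: mean centre separation grows well beyond contact
  sep <- sqrt((tr$states[, 1] - tr$states[, 5])^2 +
                (tr$states[, 2] - tr$states[, 6])^2)
  expect_gt(mean(tail(sep, length(sep) / 2)), 0.8)
  # contact lifetimes are dominated by brief encounters: the distribution
  # decays from its mode at the shortest resolvable lifetime
  cm <- dimer_contact_frames(tr, cutoff = 0.45)
  r <- rle(rowSums(cm) > 0)
  life <- r$lengths[r$values]
  expect_gt(length(life), 50)
  h <- tabulate(life, nbins = max(life))
  expect_equal(which.max(h), 1L)
  expect_true(all(diff(h[1:4]) <= 0))
})

test_that("strong native attraction dominates the equilibrium at low D_RMS", {
  m <- toy_dimer_model(eps_native = 3, eps_nonspecific = 0.5)
  p <- langevin_params(dt = 5e-5, seed = 65)
  tr <- simulate_toy_dimer(m, p, 6e5, initial = "native", thin = 10)
  expect_gt(mean(tr$drms < 0.15), 0.9)
})

test_that("the reference landscape has three populated regions separated by
           two substantial barriers", {
  ref <- toy_dimer_reference()
  p <- langevin_params(dt = ref$params$dt, seed = 66)
  tr <- simulate_toy_dimer(ref$model, p, 1.2e7, initial = "native",
                           thin = 20)
  x <- dimer_x_series(tr, hybrid_cv_params(ref$mu))
  # the inner features are ~0.1-0.3 wide in X, the outer barrier is broad
  # and flat: 0.04 bins with a 5-bin moving average resolve the former
  # while suppressing plateau noise
  pm <- project_pmf(rep(1, length(x)), x, bin_spec(-0.1, 2.6, 0.04))
  bar <- locate_barriers(pm, smooth_bins = 5)
  big <- bar[bar$height >= 0.5, ]
  expect_equal(nrow(big), 2)
  expect_lt(abs(big$position[1] - ref$x_dagger_2), 0.12)
  expect_lt(abs(big$position[2] - ref$x_dagger_1), 0.16)
  # all three states are genuinely populated
  expect_gt(mean(x < 0.15), 0.05)                          # native
  expect_gt(mean(x > 0.36 & x < 0.6), 0.02)                # intermediate
  expect_gt(mean(x > 1.0), 0.10)                           # unbound
})

test_that("umbrella bias on D_RMS confines the sampled window", {
  m <- toy_dimer_model()
  p <- langevin_params(dt = 5e-5, seed = 67)
  tr <- simulate_toy_dimer(m, p, 1e5, initial = "separate", thin = 10,
                           bias = list(center = 1.2, k = 100))
  expect_lt(abs(mean(tr$drms) - 1.2), 0.15)
  expect_lt(sd(tr$drms), 0.25)
})
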