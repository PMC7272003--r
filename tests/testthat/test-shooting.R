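test_that("select_frames samples only qualifying frames, reproducibly", {
  x <- rep(0.5, 20)
  expect_length(select_frames(x, 0.5, 0.005, 7, seed = 1), 7)
  # constructed series with exactly 12 qualifying frames
  x2 <- c(rep(0, 30), seq(0.4955, 0.5045, length.out = 12), rep(1, 30))
  got <- select_frames(x2, 0.5, 0.005, 5, seed = 2)
  expect_length(got, 5)
  expect_true(all(abs(x2[got] - 0.5) < 0.005))
  expect_equal(anyDuplicated(got), 0)
  expect_identical(got, select_frames(x2, 0.5, 0.005, 5, seed = 2))
  # all candidates returned (with a warning) when too few
  expect_warning(all12 <- select_frames(x2, 0.5, 0.005, 20, seed = 3),
                 "candidate")
  expect_length(all12, 12)
  expect_error(select_frames(rep(0, 5), 0.5, 0.005, 1), "no frames")
})

test_that("stratified selection honours the per-source frame counts", {
  set.seed(4)
  mk <- function(n) c(runif(n, 0.495, 0.505), runif(400, 1, 2))
  series <- list(together = mk(60), separate = mk(50))
  sel <- select_frames_stratified(series, c(39, 36), 0.5, seed = 5)
  expect_equal(as.vector(table(sel$source)[c("together", "separate")]),
               c(39, 36))
  sel2 <- select_frames_stratified(series, c(45, 49), 0.5, tol = 0.02,
                                   seed = 6)
  expect_equal(sum(sel2$source == "together"), 45)
  expect_equal(sum(sel2$source == "separate"), 49)
})

test_that("pair outcomes are classified by the basin definitions", {
  V <- dw(4)
  p <- langevin_params(D = 1, kT = 1, dt = 5e-4)
  prop <- langevin_propagator(V, p)
  basins <- dw_basins()
  set.seed(11)
  ens <- shoot_ensemble(runif(60, 0.495, 0.505), prop, basins,
                        max_time = 30, seed = 100, surface = 0.5)
  led <- attempt_ledger(ens)
  # classification follows from the two segment labels
  expect_true(all(ifelse(
    led$label_forward == "timeout" | led$label_backward == "timeout",
    "incomplete",
    ifelse(led$label_forward != led$label_backward, "TP", "non-TP")) ==
      led$classification))
  # swapping forward/backward labels never changes TP status
  expect_identical(led$classification,
                   ifelse(led$label_backward == "timeout" |
                            led$label_forward == "timeout", "incomplete",
                          ifelse(led$label_backward != led$label_forward,
                                 "TP", "non-TP")))
  # TPs have an odd number of recorded surface crossings
  tp <- led$classification == "TP"
  expect_true(all(led$n_crossings[tp] %% 2 == 1))
  # durations only for TPs; positive
  expect_true(all(is.na(led$duration[!tp])))
  expect_true(all(led$duration[tp] > 0))
  # a too-short time cap yields incomplete attempts, excluded from rates
  ens2 <- shoot_ensemble(runif(20, 0.495, 0.505), prop, basins,
                         max_time = 0.005, seed = 200, surface = 0.5)
  cls2 <- sapply(ens2, `[[`, "classification")
  expect_true(any(cls2 == "incomplete"))
})

test_that("launching outside the basin gap or with a wide band fails", {
  V <- dw(4)
  prop <- langevin_propagator(V, langevin_params(dt = 5e-4))
  expect_error(shoot_pair(0.1, prop, dw_basins(), 10), "basin edges")
  expect_error(shoot_pair(0.5, prop, dw_basins(), 10, band_h = 0.4),
               "band")
})

test_that("TP fraction from the barrier top is near 1/2 and decreases as the
           surface moves toward a basin", {
  V <- dw(4)
  p <- langevin_params(D = 1, kT = 1, dt = 5e-4)
  prop <- langevin_propagator(V, p)
  basins <- dw_basins()
  frac <- sapply(c(0.5, 0.35, 0.28), function(s) {
    set.seed(300)
    ens <- shoot_ensemble(runif(150, s - 0.005, s + 0.005), prop, basins,
                          max_time = 30, seed = 1000 * s, surface = s,
                          band_h = 0.04)
    tp_fraction(ens)$fraction
  })
  expect_lt(abs(frac[1] - 0.5), 3 * sqrt(0.25 / 150))
  expect_true(all(diff(frac) < 0))
})

test_that("tp_fraction arithmetic and intervals", {
  expect_equal(tp_fraction(fake_ledger(10, 65))$fraction, 10 / 75)
  expect_equal(round(tp_fraction(fake_ledger(10, 65))$fraction, 3), 0.133)
  expect_equal(tp_fraction(fake_ledger(25, 69))$fraction, 25 / 94)
  expect_equal(tp_fraction(fake_ledger(0, 10))$fraction, 0)
  expect_equal(tp_fraction(fake_ledger(12, 0))$fraction, 1)
  # incompletes excluded from the denominator
  expect_equal(tp_fraction(fake_ledger(5, 5, 10))$n_classified, 10)
  tf <- tp_fraction(fake_ledger(10, 65))
  expect_true(tf$ci[1] < tf$fraction && tf$fraction < tf$ci[2])
  expect_equal(tf$of_maximum, tf$fraction / 0.5)
  expect_error(tp_fraction(fake_ledger(0, 0, 3)), "no classified")
})

test_that("tp_durations weights paths correctly", {
  a1 <- fake_attempt("TP", inv_speed_sum = 0.5, duration = 2)  # w = 2
  a2 <- fake_attempt("TP", inv_speed_sum = 1.0, duration = 5)  # w = 1
  a3 <- fake_attempt("non-TP")
  ens <- structure(list(a1, a2, a3), class = "shooting_ensemble")
  expect_equal(tp_durations(ens), (2 * 2 + 1 * 5) / 3)
  expect_equal(tp_durations(structure(list(a1), class = "shooting_ensemble")),
               2)
  expect_equal(tp_durations(ens, weights = c(1, 1, NA)), 3.5)
  expect_error(tp_durations(structure(list(a3),
                                      class = "shooting_ensemble")), "no tra")
})

test_that("weighted shooting durations reproduce the spontaneous TP duration
           distribution", {
  V <- dw(4)
  p <- langevin_params(D = 1, kT = 1, dt = 5e-4, seed = 41)
  basins <- dw_basins()
  tr <- simulate_langevin(V, p, 1e7, 0, thin = 5)
  ev <- harvest_tps(tr$x, tr$dt, basins)
  prop <- langevin_propagator(V, langevin_params(dt = 5e-4))
  set.seed(42)
  ens <- shoot_ensemble(runif(400, 0.495, 0.505), prop, basins,
                        max_time = 30, seed = 4000, surface = 0.5)
  cls <- sapply(ens, `[[`, "classification")
  tp <- which(cls == "TP")
  w <- path_weights(ens)[tp]
  dur <- sapply(ens[tp], `[[`, "duration")
  # mean agrees within combined uncertainty
  mw <- sum(w * dur) / sum(w)
  se <- sqrt(sum((w / sum(w))^2 * (dur - mw)^2) + var(ev$duration) /
               nrow(ev))
  expect_lt(abs(mw - mean(ev$duration)), 4 * se)
  # weighted two-sample KS with the effective shooting sample size
  ord <- order(dur)
  Fw <- stats::stepfun(dur[ord], c(0, cumsum(w[ord]) / sum(w)))
  Fh <- stats::ecdf(ev$duration)
  grid <- sort(unique(c(dur, ev$duration)))
  D <- max(abs(Fw(grid) - Fh(grid)))
  n_eff <- sum(w)^2 / sum(w^2)
  n <- n_eff * nrow(ev) / (n_eff + nrow(ev))
  lam <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  kk <- 1:100
  p_ks <- max(0, min(1, 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lam^2))))
  expect_gt(p_ks, 0.01)
})

test_that("count_level_crossings counts sign changes", {
  expect_equal(count_level_crossings(c(0, 1, -1, 1, 0.2, -3), 0), 3)
  expect_equal(count_level_crossings(c(1, 2, 3), 0), 0)
  expect_equal(count_level_crossings(c(-1, 0, 1), 0), 1)  # zeros skipped
})
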