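test_that("conformations are validated", {
  expect_error(conformation("A", 1, "CA", 0, 0, 0), "two chains")
  expect_error(conformation(c("A", "B"), c(1, 1), "CA", c(0, NA), 0, 0),
               "finite")
  expect_error(conformation(c("A", "A", "B"), c(2, 1, 1), "CA",
                            1:3, 0, 0), "non-decreasing")
  cf <- toy_conformation()
  expect_s3_class(cf, "conformation")
})

test_that("build_native_set keeps all and only qualifying pairs", {
  # chains touch only at residue 2 (middle bead): sep small there
  cf <- conformation(chain = rep(c("A", "B"), each = 3),
                     resid = rep(1:3, 2), name = "CA",
                     x = c(0, 1, 2, 0, 1, 2),
                     y = c(0, 0, 0, 2, 0.4, 2), z = 0)
  ns <- build_native_set(cf, build_cutoff = 0.6)
  expect_true(all(ns$resid_a == 2 & ns$resid_b == 2))
  # infinite cutoff on a 3-atom-per-chain toy: all 9 intermolecular pairs
  ns_all <- build_native_set(cf, build_cutoff = Inf)
  expect_equal(nrow(ns_all), 9)
  # count agrees with an O(N^2) loop oracle at 0.6 nm on the dimer fixture
  m <- toy_dimer_model()
  nat <- dimer_native_conformation(m)
  ns_d <- build_native_set(nat, residue_range = c(3, 9), build_cutoff = 0.6)
  a <- nat[nat$chain == "A" & nat$resid >= 3 & nat$resid <= 9, ]
  b <- nat[nat$chain == "B" & nat$resid >= 3 & nat$resid <= 9, ]
  cnt <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    if (sqrt(sum((a[i, c("x", "y", "z")] - b[j, c("x", "y", "z")])^2)) < 0.6)
      cnt <- cnt + 1
  expect_equal(nrow(ns_d), cnt)
  # empty set is an error: the coordinate would be undefined
  far <- transform_conformation(cf, translation = c(0, 0, 0))
  far[far$chain == "B", c("y")] <- 50
  expect_error(build_native_set(far, build_cutoff = 0.6), "empty")
})

test_that("drms matches hand arithmetic and a brute-force oracle", {
  m <- toy_dimer_model()
  nat <- dimer_native_conformation(m)
  ns <- dimer_native_set(m)
  expect_equal(drms(nat, ns), 0)
  # two pairs deviating by +0.1 and -0.1 -> 0.1 exactly
  ns2 <- ns[1:2, ]
  class(ns2) <- class(ns)
  conf2 <- nat
  key <- paste(conf2$chain, conf2$resid)
  i1 <- which(key == paste(ns2$chain_b[1], ns2$resid_b[1]))
  # move the two B-side atoms along the pair axis by +/- 0.1
  move <- function(conf, ns_row, delta) {
    ia <- which(conf$chain == ns_row$chain_a & conf$resid == ns_row$resid_a)
    ib <- which(conf$chain == ns_row$chain_b & conf$resid == ns_row$resid_b)
    u <- unlist(conf[ib, c("x", "y", "z")] - conf[ia, c("x", "y", "z")])
    u <- u / sqrt(sum(u^2))
    conf[ib, c("x", "y", "z")] <- conf[ib, c("x", "y", "z")] + delta * u
    conf
  }
  conf2 <- move(conf2, ns2[1, ], +0.1)
  conf2 <- move(conf2, ns2[2, ], -0.1)
  expect_equal(drms(conf2, ns2), 0.1, tolerance = 1e-12)
  # random conformations against the independent loop oracle
  for (seed in 1:3) {
    rc <- random_conformation(5, seed)
    ns_r <- build_native_set(random_conformation(5, seed + 100),
                             build_cutoff = Inf)
    expect_equal(drms(rc, ns_r), oracle_drms(rc, ns_r), tolerance = 1e-12)
  }
  # missing atom names the offending pair
  short <- nat[!(nat$chain == "B" & nat$resid == 4), ]
  class(short) <- class(nat)
  expect_error(drms(short, ns), "B4")
})

test_that("drms is invariant under rigid-body motion", {
  rc <- random_conformation(6, 2)
  ns <- build_native_set(random_conformation(6, 99), build_cutoff = Inf)
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- transform_conformation(rc, R, c(1.5, -2, 0.3))
  expect_equal(drms(moved, ns), drms(rc, ns), tolerance = 1e-10)
})

test_that("crossing angle reproduces planar, rotated and mirrored geometry", {
  # cis planar: 0; trans planar: pi
  anch <- data.frame(chain = c("A", "A", "B", "B"), resid = c(1, 2, 2, 1),
                     name = "CA")
  mk <- function(p1, p2, p3, p4) {
    # rows stored in residue order; anchors select them in dihedral order
    xyz <- rbind(p1, p2, p4, p3)
    conformation(chain = c("A", "A", "B", "B"), resid = c(1, 2, 1, 2),
                 name = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  cis <- mk(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(crossing_angle(cis, anch), 0)
  trans <- mk(c(0, 1, 0), c(1, 1, 0), c(2, 0, 0), c(3, 0, 0))
  expect_equal(abs(crossing_angle(trans, anch)), pi)
  # rotating the last point about the central bond changes the angle by phi
  base <- mk(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  a0 <- crossing_angle(base, anch)
  for (phi in c(0.3, -0.9, 2.2)) {
    rot <- base
    # rotate the terminal anchor (B residue 1, stored row 3) about the
    # x-axis, i.e. about the central bond
    rot[3, c("x", "y", "z")] <- c(1, cos(phi), sin(phi))
    a1 <- crossing_angle(rot, anch)
    d <- (a1 - a0 + pi) %% (2 * pi) - pi
    expect_equal(d, -phi, tolerance = 1e-10)
  }
  # mirror reflection flips the sign
  mir <- base
  mir$z <- -mir$z
  expect_equal(crossing_angle(mir, anch), -a0, tolerance = 1e-12)
  # collinear anchors are rejected
  lin <- mk(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(crossing_angle(lin, anch), "collinear")
})

test_that("hybrid coordinate arithmetic", {
  expect_equal(hybrid_cv(1.0, 0, hybrid_cv_params(0.1)), 1.0)
  # the second-barrier value arises from D_RMS = 0.1 nm, theta = 0.15 rad
  expect_equal(hybrid_cv(0.1, 0.15, hybrid_cv_params(0.1)), 0.115)
  # mu = 0 reduces to D_RMS for any angle
  th <- seq(-pi, pi, by = 0.5)
  expect_equal(hybrid_cv(0.7, th, hybrid_cv_params(0)), rep(0.7, length(th)))
  # linear in each argument, monotone in D_RMS
  expect_equal(hybrid_cv(0.2 + 0.3, 0.1, 0.1),
               hybrid_cv(0.2, 0.1, 0.1) + 0.3)
  expect_error(hybrid_cv_params(-0.1))
})

test_that("contact maps match the brute-force distance loop", {
  m <- toy_dimer_model()
  # far apart: all false
  far <- dimer_conformation(m, c(0, 0, 0, 0, 0, 2.5, 0, 0))
  expect_false(any(contact_map(far)))
  # a single pair just inside the cutoff
  near <- toy_conformation(n = 3, sep = 10)
  near[near$chain == "B" & near$resid == 2, "y"] <- 0.44
  cm <- contact_map(near, 0.45)
  expect_equal(sum(cm), 1)
  expect_true(cm["2", "2"])
  # strictly-less comparison at the cutoff
  near[near$chain == "B" & near$resid == 2, "y"] <- 0.45
  expect_equal(sum(contact_map(near, 0.45)), 0)
  # random frames against the O(N^2) oracle; monotone in cutoff
  for (seed in 4:6) {
    rc <- random_conformation(6, seed)
    for (cut in c(0.3, 0.6, 1.2)) {
      got <- contact_map(rc, cut)
      expect_equal(unclass(got)[, ], oracle_contact_map(rc, cut),
                   ignore_attr = TRUE)
    }
    small <- contact_map(rc, 0.4)
    big <- contact_map(rc, 0.9)
    expect_true(all(big[small]))        # set inclusion
    expect_false(any(contact_map(rc, 0)))
  }
})

test_that("PDB text round-trips a conformation", {
  cf <- random_conformation(4, 9)
  f <- tempfile(fileext = ".pdb")
  write_conformation_pdb(cf, f)
  back <- read_conformation_pdb(f)
  expect_equal(back$chain, cf$chain)
  expect_equal(back$resid, cf$resid)
  expect_equal(back$x, cf$x, tolerance = 1e-3)  # PDB precision 0.1 pm
  expect_equal(back$z, cf$z, tolerance = 1e-3)
})

test_that("cv_series assembles aligned tables", {
  m <- toy_dimer_model()
  confs <- list(dimer_native_conformation(m),
                dimer_conformation(m, dimer_separate_state(m)))
  ns <- dimer_native_set(m)
  tab <- cv_series(confs, ns, dimer_anchors(m), hybrid_cv_params(0.1), dt = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$drms[1], 0)
  expect_equal(tab$x, tab$drms + 0.1 * tab$theta)
  expect_equal(tab$time, c(0, 2))
})
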