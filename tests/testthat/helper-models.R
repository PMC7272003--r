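# shared fixtures: analytic models and small reference objects built in code

dw <- function(b = 4, k_conf = 100) double_well(c(0, 1), b, k_conf = k_conf)

tw <- function(b1 = 4, b2 = 6) triple_well(c(0, 0.4, 1.8), c(b1, b2))

dw_basins <- function() basin_spec(a = c(-0.4, 0.2), b = c(0.8, 1.4))

# equilibrium quantities of a 1D model by quadrature on the analytic density
analytic_peq <- function(model, at, kT = 1) {
  bd <- boltzmann_density(model, kT)
  stats::approx(bd$x, bd$density, at)$y
}

analytic_mass <- function(model, lo, hi, kT = 1) {
  bd <- boltzmann_density(model, kT)
  keep <- bd$x >= lo & bd$x <= hi
  x <- bd$x[keep]; y <- bd$density[keep]
  sum((y[-1] + y[-length(y)]) * diff(x)) / 2
}

# a tiny two-chain conformation: n beads per chain on parallel lines
toy_conformation <- function(n = 3, sep = 0.4, shift = 0) {
  conformation(chain = rep(c("A", "B"), each = n),
               resid = rep(seq_len(n), 2),
               name = "CA",
               x = c(seq_len(n) * 0.5, seq_len(n) * 0.5 + shift),
               y = c(rep(0, n), rep(sep, n)),
               z = 0)
}

random_conformation <- function(n = 5, seed = 1) {
  set.seed(seed)
  conformation(chain = rep(c("A", "B"), each = n),
               resid = rep(seq_len(n), 2),
               name = "CA",
               x = stats::runif(2 * n, 0, 2),
               y = stats::runif(2 * n, 0, 2),
               z = stats::runif(2 * n, 0, 2))
}

# brute-force O(N^2) oracles, written independently of the implementation
oracle_drms <- function(conf, ns) {
  tot <- 0
  for (r in seq_len(nrow(ns))) {
    a <- conf[conf$chain == ns$chain_a[r] & conf$resid == ns$resid_a[r] &
                conf$name == ns$name_a[r], ]
    b <- conf[conf$chain == ns$chain_b[r] & conf$resid == ns$resid_b[r] &
                conf$name == ns$name_b[r], ]
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    tot <- tot + (d - ns$r0[r])^2
  }
  sqrt(tot / nrow(ns))
}

oracle_contact_map <- function(conf, cutoff) {
  ch <- sort(unique(conf$chain))
  a <- conf[conf$chain == ch[1] & conf$heavy, ]
  b <- conf[conf$chain == ch[2] & conf$heavy, ]
  ra <- sort(unique(a$resid)); rb <- sort(unique(b$resid))
  m <- matrix(FALSE, length(ra), length(rb))
  for (i in seq_along(ra)) for (j in seq_along(rb)) {
    ai <- a[a$resid == ra[i], ]; bj <- b[b$resid == rb[j], ]
    for (u in seq_len(nrow(ai))) for (v in seq_len(nrow(bj))) {
      d <- sqrt((ai$x[u] - bj$x[v])^2 + (ai$y[u] - bj$y[v])^2 +
                  (ai$z[u] - bj$z[v])^2)
      if (d < cutoff) m[i, j] <- TRUE
    }
  }
  m
}

# build a synthetic shooting_attempt for arithmetic tests
fake_attempt <- function(classification = "TP", inv_speed_sum = 1,
                         duration = 1, n_crossings = 1) {
  structure(list(x0 = 0.5, surface = 0.5, band_h = 0.05,
                 label_forward = if (classification == "TP") "B" else "A",
                 label_backward = "A",
                 classification = classification,
                 cross_speeds = rep(1, n_crossings),
                 n_crossings = n_crossings,
                 inv_speed_sum = inv_speed_sum,
                 duration = duration, seed = NA_integer_),
            class = "shooting_attempt")
}

fake_ledger <- function(n_tp, n_non_tp, n_incomplete = 0) {
  data.frame(classification = c(rep("TP", n_tp), rep("non-TP", n_non_tp),
                                rep("incomplete", n_incomplete)))
}
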