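#' Parameters for overdamped Langevin dynamics
#'
#' Overdamped (high-friction) Euler--Maruyama dynamics: there are no
#' momenta, and the single-step displacement has standard deviation
#' `sqrt(2 D dt)`. [simulate_langevin()] refuses time steps whose single-step
#' displacement exceeds one tenth of the narrowest well width of the model,
#' which keeps the discretization error of the stationary density small.
#'
#' @param D diffusion coefficient (coordinate units^2 / time).
#' @param kT thermal energy.
#' @param dt integration time step.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#'   Identical seeds give identical trajectories.
#' @return object of class `langevin_params`.
#' @export
langevin_params <- function(D = 1, kT = 1, dt = 1e-4, seed = NULL) {
  stopifnot(D > 0, kT >= 0, dt > 0)
  structure(list(D = D, kT = kT, dt = dt, seed = seed,
                 regime = "overdamped"),
            class = "langevin_params")
}

step_sd <- function(params) sqrt(2 * params$D * params$dt)

check_timestep <- function(model, params) {
  if (!length(model$knots) || length(model$knots) < 2L) return(invisible())
  wmin <- min(diff(model$knots))
  if (step_sd(params) >= wmin / 10)
    stop(sprintf(paste0("time step too large: single-step displacement sd ",
                        "%.3g >= %.3g (1/10 of the narrowest well width)"),
                 step_sd(params), wmin / 10))
  invisible()
}

#' Simulate overdamped Langevin dynamics on a 1D potential
#'
#' Euler--Maruyama integration of `dx = -(D/kT) V'(x) dt + sqrt(2 D dt) xi`.
#' In the zero-temperature limit (`kT -> 0` with the ratio `D/kT` held
#' finite via `mobility`) the dynamics become deterministic steepest descent.
#'
#' @param model a [multi_well_potential()] (or flat) `potential_model`.
#' @param params a [langevin_params()] object.
#' @param n_steps number of integration steps.
#' @param initial starting coordinate (must lie in the model domain).
#' @param thin store every `thin`-th frame (frame 0, the initial point, is
#'   always stored).
#' @param bias optional harmonic umbrella bias, a list with elements
#'   `center` and `k`.
#' @param mobility ratio D/kT used for the drift when `kT = 0` (the
#'   deterministic limit); ignored otherwise.
#' @return object of class `cv_trajectory`: list with the stored coordinate
#'   series `x`, the record interval `dt` (equal to `params$dt * thin`), and
#'   the provenance (`model`, `params`, `bias`).
#' @export
simulate_langevin <- function(model, params, n_steps, initial, thin = 1L,
                              bias = NULL, mobility = 1) {
  stopifnot(inherits(model, "potential_model"),
            inherits(params, "langevin_params"))
  if (initial < model$domain[1] || initial > model$domain[2])
    stop("initial coordinate outside the model domain")
  if (params$kT > 0) check_timestep(model, params)
  if (!is.null(params$seed)) set.seed(params$seed)
  bc <- 0; bk <- 0
  if (!is.null(bias)) { bc <- bias$center; bk <- bias$k }
  kT_eff <- if (params$kT > 0) params$kT else 1 / mobility
  D_eff <- if (params$kT > 0) params$D else 0
  x <- if (params$kT > 0) {
    sim_overdamped_cpp(model$knots, model$values, model$k_conf,
                       params$D, params$kT, params$dt, n_steps, initial,
                       as.integer(thin), bc, bk)
  } else {
    # deterministic steepest descent: drift mobility * (-V'), no noise
    xx <- numeric(floor(n_steps / thin) + 1)
    cur <- initial; xx[1] <- cur; i <- 2L
    for (s in seq_len(n_steps)) {
      g <- potential_grad(model, cur)
      if (bk > 0) g <- g + bk * (cur - bc)
      cur <- cur - mobility * g * params$dt
      if (s %% thin == 0) { xx[i] <- cur; i <- i + 1L }
    }
    xx
  }
  structure(list(x = as.numeric(x), dt = params$dt * thin,
                 n_steps = n_steps, thin = as.integer(thin),
                 model = model, params = params, bias = bias),
            class = "cv_trajectory")
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat("<cv_trajectory>", length(x$x), "frames, record interval", x$dt, "\n")
  invisible(x)
}

#' Basin specification on a one-dimensional coordinate
#'
#' Two disjoint closed intervals on the reaction coordinate: basin A at low
#' coordinate values and basin B at high values. The dividing surface used
#' for shooting must lie strictly between `a[2]` and `b[1]`.
#'
#' @param a,b numeric length-2 vectors `c(lo, hi)` for basins A and B.
#' @return object of class `basin_spec`.
#' @export
basin_spec <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] < a[2], b[1] < b[2])
  if (a[2] >= b[1]) stop("basins must be disjoint with A below B")
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "basin_spec")
}

# Per-frame basin code (1 = A, 2 = B, 0 = neither) and the same codes with
# gaps filled by the last visited basin (0 before any basin is reached).
basin_codes <- function(x, basins) {
  code <- integer(length(x))
  code[x >= basins$a[1] & x <= basins$a[2]] <- 1L
  code[x >= basins$b[1] & x <= basins$b[2]] <- 2L
  idx <- cumsum(code != 0L)
  filled <- integer(length(x))
  nz <- code[code != 0L]
  filled[idx > 0L] <- nz[idx[idx > 0L]]
  list(code = code, filled = filled)
}

#' Transition statistics of an equilibrium trajectory
#'
#' Assigns every frame to basin A, basin B, or neither, classifies the
#' in-between segments as transition paths (flanking basins differ) or
#' failed excursions, and tabulates transition events with their
#' transition-path durations.
#'
#' @param x numeric coordinate series at uniform spacing.
#' @param dt time between frames.
#' @param basins a [basin_spec()].
#' @return list with `events` (data.frame: `time`, `from`, `to`,
#'   `duration` of the connecting transition path), per-basin residence
#'   times `time_a`/`time_b` (time since last in that basin, the
#'   denominator of the transition-count rate), in-interval occupancies
#'   `occ_a`/`occ_b`, logical per-frame vectors `tp_frame` (on a transition
#'   path) and the basin `code`.
#' @export
transition_stats <- function(x, dt, basins) {
  bc <- basin_codes(x, basins)
  code <- bc$code; filled <- bc$filled
  n <- length(x)
  r <- rle(filled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tp_frame <- logical(n)
  ev_time <- ev_from <- ev_to <- ev_dur <- numeric(0)
  # runs of the filled sequence: a change 1->2 or 2->1 marks a transition;
  # the TP is the trailing run of out-of-basin frames before the change
  for (k in seq_along(r$values)[-1]) {
    from <- r$values[k - 1L]; to <- r$values[k]
    if (from == 0L || to == 0L || from == to) next
    # frames between last occupancy of `from` and first occupancy of `to`
    i1 <- ends[k - 1L]
    last_in <- max(which(code[starts[k - 1L]:i1] == from)) + starts[k - 1L] - 1L
    first_in <- starts[k]
    if (first_in > last_in + 1L) tp_frame[(last_in + 1L):(first_in - 1L)] <- TRUE
    ev_time <- c(ev_time, (first_in - 1L) * dt)
    ev_from <- c(ev_from, from); ev_to <- c(ev_to, to)
    ev_dur <- c(ev_dur, (first_in - last_in - 1L) * dt)
  }
  list(events = data.frame(time = ev_time, from = ev_from, to = ev_to,
                           duration = ev_dur),
       time_a = sum(filled == 1L) * dt,
       time_b = sum(filled == 2L) * dt,
       occ_a = mean(code == 1L), occ_b = mean(code == 2L),
       tp_frame = tp_frame, code = code, filled = filled, dt = dt)
}

#' Brute-force rate constants by transition counting
#'
#' The independent kinetics oracle: simulate a long unbiased trajectory and
#' count A->B and B->A transitions directly. The rate `k_AB` is the number
#' of A->B events divided by the total time during which the system was
#' last in A. Standard errors come from a block bootstrap over contiguous
#' trajectory blocks.
#'
#' @param model a `potential_model`.
#' @param params a [langevin_params()].
#' @param n_steps simulation length in steps.
#' @param basins a [basin_spec()].
#' @param initial starting coordinate; defaults to the centre of basin A.
#' @param thin frame-storage stride.
#' @param n_blocks,n_boot block count and bootstrap resamples.
#' @param min_transitions below this many events in either direction the
#'   result is flagged `unreliable`.
#' @return list with `k_ab`, `k_ba`, bootstrap `se_ab`/`se_ba`, event
#'   counts, occupancies, the underlying [transition_stats()], and an
#'   `unreliable` flag.
#' @export
brute_force_rates <- function(model, params, n_steps, basins,
                              initial = NULL, thin = 10L, n_blocks = 20L,
                              n_boot = 200L, min_transitions = 50L) {
  if (is.null(initial)) initial <- mean(basins$a)
  traj <- simulate_langevin(model, params, n_steps, initial, thin = thin)
  res <- rates_from_trajectory(traj$x, traj$dt, basins, n_blocks, n_boot)
  res$unreliable <- with(res, n_ab < min_transitions || n_ba < min_transitions)
  if (res$unreliable)
    warning("fewer than ", min_transitions,
            " transitions in at least one direction; rates unreliable")
  res$trajectory <- traj
  res
}

#' @rdname brute_force_rates
#' @param x,dt a precomputed coordinate series and its frame interval, for
#'   counting rates on an existing trajectory.
#' @export
rates_from_trajectory <- function(x, dt, basins, n_blocks = 20L,
                                  n_boot = 200L) {
  ts <- transition_stats(x, dt, basins)
  n_ab <- sum(ts$events$from == 1L)
  n_ba <- sum(ts$events$from == 2L)
  k_ab <- n_ab / ts$time_a
  k_ba <- n_ba / ts$time_b
  # block bootstrap: partition frames into contiguous blocks, resample
  n <- length(x)
  bl <- pmin(floor((seq_len(n) - 1L) / ceiling(n / n_blocks)) + 1L, n_blocks)
  per_block <- function(idx) {
    sub <- transition_stats(x[bl %in% idx], dt, basins)
    c(sum(sub$events$from == 1L), sum(sub$events$from == 2L),
      sub$time_a, sub$time_b)
  }
  stats <- vapply(seq_len(n_blocks), function(b) per_block(b), numeric(4))
  boot <- replicate(n_boot, {
    pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
    s <- rowSums(stats[, pick, drop = FALSE])
    c(if (s[3] > 0) s[1] / s[3] else NA_real_,
      if (s[4] > 0) s[2] / s[4] else NA_real_)
  })
  list(k_ab = k_ab, k_ba = k_ba,
       se_ab = stats::sd(boot[1, ], na.rm = TRUE),
       se_ba = stats::sd(boot[2, ], na.rm = TRUE),
       boot_ab = boot[1, ], boot_ba = boot[2, ],
       n_ab = n_ab, n_ba = n_ba,
       occ_a = ts$occ_a, occ_b = ts$occ_b,
       stats = ts)
}

#' Harvest spontaneous transition paths from an equilibrium trajectory
#'
#' Returns the durations (and frame index ranges) of every spontaneous
#' barrier crossing in an unbiased run; the unbiased reference ensemble
#' against which the weighted shooting ensemble is validated.
#'
#' @inheritParams rates_from_trajectory
#' @param direction `"both"`, `"ab"`, or `"ba"`.
#' @return data.frame of events with `from`, `to`, `duration`.
#' @export
harvest_tps <- function(x, dt, basins, direction = c("both", "ab", "ba")) {
  direction <- match.arg(direction)
  ev <- transition_stats(x, dt, basins)$events
  if (direction == "ab") ev <- ev[ev$from == 1L, ]
  if (direction == "ba") ev <- ev[ev$from == 2L, ]
  ev
}

#' Mean-square displacement of a trajectory
#'
#' @param x coordinate series at uniform spacing `dt`.
#' @param lags integer vector of frame lags.
#' @param dt frame interval.
#' @return data.frame with `lag_time` and `msd`.
#' @export
msd <- function(x, lags, dt = 1) {
  data.frame(lag_time = lags * dt,
             msd = vapply(lags, function(L) mean((x[-seq_len(L)] -
                            x[seq_len(length(x) - L)])^2), numeric(1)))
}
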