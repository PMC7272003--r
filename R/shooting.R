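#' Propagators for dividing-surface shooting
#'
#' A propagator bundles a synthetic model with integration parameters and
#' exposes the single contract the shooting machinery needs: given a
#' starting state and the basin spec, run until the reaction coordinate
#' enters a basin or `max_time` is reached, recording crossings of the
#' dividing surface and the time spent in a narrow band around it.
#'
#' For overdamped models there are no momenta, so a "conjugate momenta"
#' pair is realized as two trajectories from the same frame with
#' independent noise streams; the pair is still a valid equilibrium path
#' through the launch point, which is what the rate estimator requires.
#'
#' @param model a [multi_well_potential()] / [toy_dimer_model()].
#' @param params a [langevin_params()].
#' @param mu hybrid-CV coefficient (dimer propagator only).
#' @return a `propagator` object.
#' @export
langevin_propagator <- function(model, params) {
  stopifnot(inherits(model, "potential_model"),
            inherits(params, "langevin_params"))
  check_timestep(model, params)
  structure(list(kind = "langevin1d", model = model, params = params,
                 dt = params$dt), class = "propagator")
}

#' @rdname langevin_propagator
#' @export
dimer_propagator <- function(model, params, mu = 0.1) {
  stopifnot(inherits(model, "toy_dimer_model"),
            inherits(params, "langevin_params"))
  structure(list(kind = "toy_dimer", model = model, params = params,
                 mu = mu, dt = params$dt), class = "propagator")
}

# run one segment; returns label (0/1/2), entry time, crossing speeds of
# `level`, the coordinate after the first step, and the thinned CV path
run_segment <- function(prop, state, level, basins, max_steps, thin,
                        band_h) {
  if (prop$kind == "langevin1d") {
    m <- prop$model; p <- prop$params
    seg <- shoot_segment_cpp(m$knots, m$values, m$k_conf, p$D, p$kT, p$dt,
                             as.numeric(state), level, basins$a[2],
                             basins$b[1], max_steps, as.integer(thin),
                             band_h)
    seg$x <- seg$path
    seg$states <- matrix(seg$path, ncol = 1L)
  } else {
    par <- dimer_cpp_par(prop$model, prop$params)
    seg <- shoot_dimer_cpp(par, as.numeric(state), prop$mu, level,
                           basins$a[2], basins$b[1], max_steps,
                           as.integer(thin), band_h)
  }
  seg$x_first <- if (length(seg$x) >= 2L) seg$x[2L] else NA_real_
  seg
}

# default half-width of the crossing band: a few single-step displacement
# standard deviations, so one barrier transit spans several frames
default_band_h <- function(prop) {
  D <- if (prop$kind == "langevin1d") prop$params$D else prop$model$D_trans
  4 * sqrt(2 * D * prop$params$dt)
}

#' Select shooting frames near a dividing surface
#'
#' Uniform random sample, without replacement, of frames whose coordinate
#' lies within `tol` of the dividing-surface value (strict `<`).
#'
#' @param x coordinate series.
#' @param x_target dividing-surface value.
#' @param tol selection tolerance (default 0.005).
#' @param n_frames frames to draw; if more than the number of candidates,
#'   all candidates are returned with a warning.
#' @param seed RNG seed for reproducible selection (`NULL` = current
#'   stream).
#' @return integer frame indices.
#' @export
select_frames <- function(x, x_target, tol = 0.005, n_frames, seed = NULL) {
  cand <- which(abs(x - x_target) < tol)
  if (!length(cand))
    stop("no frames within ", tol, " of ", x_target)
  if (!is.null(seed)) set.seed(seed)
  if (length(cand) <= n_frames) {
    if (length(cand) < n_frames)
      warning("only ", length(cand), " candidate frames within tolerance; ",
              "returning all of them")
    return(cand)
  }
  sort(sample(cand, n_frames))
}

#' @rdname select_frames
#' @param series_list named list of coordinate series (one per independent
#'   simulation, e.g. "start together" and "start separate").
#' @param counts frames to draw from each source (same length/order).
#' @return for the stratified form, a data.frame with `source` and `frame`.
#' @export
select_frames_stratified <- function(series_list, counts, x_target,
                                     tol = 0.005, seed = NULL) {
  stopifnot(length(series_list) == length(counts))
  if (!is.null(seed)) set.seed(seed)
  src <- names(series_list)
  if (is.null(src)) src <- as.character(seq_along(series_list))
  out <- lapply(seq_along(series_list), function(i) {
    idx <- select_frames(series_list[[i]], x_target, tol, counts[i])
    data.frame(source = src[i], frame = idx, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Launch one shooting pair from a dividing-surface frame
#'
#' Two trajectory segments are launched from the frame (for inertialess
#' overdamped dynamics, with independent noise; the pair plays the role of
#' the forward/backward pair with sign-reversed Maxwell-Boltzmann
#' velocities). Each segment runs until the reaction coordinate enters
#' basin A or basin B (entry tested against the inner basin edges, with
#' the crossing time interpolated linearly between steps) or until
#' `max_time`. The attempt is a transition path when the two segments
#' terminate in different basins; if either segment times out the attempt
#' is `incomplete`.
#'
#' Crossings of the dividing surface are recorded in two ways. Individual
#' sign changes of `X - surface` between steps are logged with their
#' single-step finite-difference speeds (`cross_speeds`; used for parity
#' diagnostics). The quantity `sum_i 1/|v_i|` that enters the rate
#' estimator and the path weights is measured on a band of half-width
#' `band_h` around the surface: each transit of the band at speed `v`
#' spends `2 band_h / |v|` inside it, so the summed reciprocal speeds
#' equal (occupation time of the band) / (2 band_h). For diffusive
#' dynamics the single-step speeds are noise-dominated (the reciprocal
#' sum then carries a scale-free bias), while the band measurement
#' converges; the default half-width is four single-step displacement
#' standard deviations.
#'
#' @param state launch state (coordinate for 1D models, length-8 state for
#'   the toy dimer).
#' @param propagator a [langevin_propagator()] or [dimer_propagator()].
#' @param basins a [basin_spec()]; the launch coordinate must lie strictly
#'   between the inner basin edges.
#' @param max_time per-segment time cap (time units).
#' @param seed RNG seed for the pair.
#' @param thin storage stride of the returned CV paths.
#' @param surface the dividing-surface value X-dagger at which crossings
#'   are recorded - one fixed level common to all attempts (frames are
#'   selected within a small tolerance of it). Defaults to the attempt's
#'   own launch value, which is only appropriate when launching exactly
#'   at the surface.
#' @param band_h half-width of the crossing band (CV units); `NULL` for
#'   the default of 4 step standard deviations. Must leave the band clear
#'   of both basin edges.
#' @return object of class `shooting_attempt` with the launch value `x0`,
#'   per-segment termination labels (`"A"`, `"B"`, `"timeout"`),
#'   `classification` (`"TP"`, `"non-TP"`, `"incomplete"`), crossing
#'   speeds, `duration` (TPs only: forward + backward time to basin), and
#'   the thinned forward/backward CV paths.
#' @export
shoot_pair <- function(state, propagator, basins, max_time, seed = NULL,
                       thin = 10L, surface = NULL, band_h = NULL) {
  stopifnot(inherits(propagator, "propagator"),
            inherits(basins, "basin_spec"))
  if (!is.null(seed)) set.seed(seed)
  x0 <- launch_cv(propagator, state)
  if (x0 <= basins$a[2] || x0 >= basins$b[1])
    stop("launch frame (X = ", signif(x0, 4),
         ") is not between the basin edges")
  if (is.null(surface)) surface <- x0
  if (is.null(band_h)) band_h <- default_band_h(propagator)
  if (surface - band_h <= basins$a[2] || surface + band_h >= basins$b[1])
    stop("crossing band [", signif(surface - band_h, 4), ", ",
         signif(surface + band_h, 4), "] reaches a basin edge; reduce ",
         "band_h or widen the basin gap")
  max_steps <- ceiling(max_time / propagator$dt)
  fw <- run_segment(propagator, state, surface, basins, max_steps, thin,
                    band_h)
  bw <- run_segment(propagator, state, surface, basins, max_steps, thin,
                    band_h)
  lab <- c("timeout", "A", "B")
  label_f <- lab[fw$label + 1L]
  label_b <- lab[bw$label + 1L]
  classification <- if (fw$label == 0L || bw$label == 0L) "incomplete"
    else if (fw$label != bw$label) "TP" else "non-TP"
  # crossings of the surface along the concatenated path rev(backward) +
  # forward; each branch detects its own crossings (the sign is seeded
  # with the launch offset, so the interval adjoining the junction is
  # covered). Only when the launch point sits exactly on the surface is
  # the junction itself a potential crossing, taken centrally across 2 dt.
  speeds <- c(bw$cross_speeds, fw$cross_speeds)
  if (x0 == surface && fw$first_sign != 0L && bw$first_sign != 0L &&
      fw$first_sign != bw$first_sign)
    speeds <- c(abs(fw$x_first - bw$x_first) / (2 * propagator$dt), speeds)
  occ <- fw$occupation + bw$occupation +
    propagator$dt * (abs(x0 - surface) < band_h)  # launch frame, once
  duration <- if (classification == "TP") fw$time + bw$time else NA_real_
  structure(list(x0 = x0, state = state, surface = surface,
                 band_h = band_h,
                 label_forward = label_f, label_backward = label_b,
                 classification = classification,
                 cross_speeds = speeds, n_crossings = length(speeds),
                 inv_speed_sum = occ / (2 * band_h),
                 duration = duration, seed = seed,
                 forward = fw, backward = bw),
            class = "shooting_attempt")
}

launch_cv <- function(propagator, state) {
  if (propagator$kind == "langevin1d") return(as.numeric(state)[1])
  par <- dimer_cpp_par(propagator$model, propagator$params)
  cv <- dimer_cv_cpp(par, matrix(as.numeric(state), nrow = 1L))
  cv$drms[1] + propagator$mu * cv$theta[1]
}

#' @export
print.shooting_attempt <- function(x, ...) {
  cat("<shooting_attempt>", x$classification, " (forward ->",
      x$label_forward, ", backward ->", x$label_backward, ");",
      x$n_crossings, "crossings of X0 =", signif(x$x0, 4), "\n")
  invisible(x)
}

#' Shoot an ensemble of pairs
#'
#' Launches one [shoot_pair()] per row of `states`, with per-attempt seeds
#' spawned deterministically from `seed` (attempt i uses `seed + i`), so
#' the ensemble is reproducible and the result is independent of execution
#' order.
#'
#' @param states list of launch states (or a numeric vector of 1D launch
#'   coordinates).
#' @param propagator,basins,max_time,thin,surface,band_h passed to
#'   [shoot_pair()].
#' @param seed master seed.
#' @return list of `shooting_attempt` objects (class `shooting_ensemble`).
#' @export
shoot_ensemble <- function(states, propagator, basins, max_time, seed = 1L,
                           thin = 10L, surface = NULL, band_h = NULL) {
  if (is.numeric(states) && is.null(dim(states))) states <- as.list(states)
  attempts <- lapply(seq_along(states), function(i)
    shoot_pair(states[[i]], propagator, basins, max_time,
               seed = seed + i, thin = thin, surface = surface,
               band_h = band_h))
  class(attempts) <- "shooting_ensemble"
  attempts
}

#' Fraction of transition paths in a shooting ensemble
#'
#' `#TP / #classified` with a Wilson binomial interval; timeouts are not
#' classified and are excluded from the denominator. For diffusive
#' dynamics on an ideal reaction coordinate the maximum attainable
#' fraction is 1/2, so the fraction is also reported relative to 0.5.
#'
#' @param attempts a `shooting_ensemble` (list of attempts) or a ledger
#'   data.frame with a `classification` column.
#' @param conf confidence level of the Wilson interval.
#' @return list with `fraction`, `n_tp`, `n_classified`, `ci` (Wilson),
#'   and `of_maximum` (= fraction / 0.5).
#' @export
tp_fraction <- function(attempts, conf = 0.95) {
  cls <- attempt_classifications(attempts)
  n_tp <- sum(cls == "TP")
  n_cl <- sum(cls %in% c("TP", "non-TP"))
  if (n_cl < 1L) stop("no classified attempts")
  f <- n_tp / n_cl
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n_cl
  ctr <- (f + z^2 / (2 * n_cl)) / den
  hw <- z * sqrt(f * (1 - f) / n_cl + z^2 / (4 * n_cl^2)) / den
  list(fraction = f, n_tp = n_tp, n_classified = n_cl,
       ci = c(ctr - hw, ctr + hw), of_maximum = f / 0.5)
}

attempt_classifications <- function(attempts) {
  if (is.data.frame(attempts)) return(attempts$classification)
  vapply(attempts, `[[`, character(1), "classification")
}

#' Weighted mean transition-path duration
#'
#' `sum(w_i tau_i) / sum(w_i)` over the transition paths, with the
#' recrossing-corrected path weights (see [path_weight()]); equal weights
#' give the arithmetic mean.
#'
#' @param attempts a `shooting_ensemble`.
#' @param weights per-attempt weights aligned with `attempts`; defaults to
#'   the Eq-style recrossing weights computed by [path_weights()].
#' @return weighted mean duration (time units).
#' @export
tp_durations <- function(attempts, weights = NULL) {
  cls <- attempt_classifications(attempts)
  tp <- which(cls == "TP")
  if (!length(tp)) stop("no transition paths in the ensemble")
  if (is.null(weights)) weights <- path_weights(attempts)
  d <- vapply(attempts[tp], `[[`, numeric(1), "duration")
  w <- weights[tp]
  sum(w * d) / sum(w)
}

#' Attempt ledger
#'
#' Per-attempt summary table mirroring the bookkeeping of a shooting
#' campaign: outcome labels, crossing counts, normalized weights and
#' durations, sorted by attempt id.
#'
#' @param attempts a `shooting_ensemble`.
#' @return data.frame with one row per attempt.
#' @export
attempt_ledger <- function(attempts) {
  w <- tryCatch(path_weights(attempts), error = function(e)
    rep(NA_real_, length(attempts)))
  data.frame(
    attempt = seq_along(attempts),
    x0 = vapply(attempts, `[[`, numeric(1), "x0"),
    label_forward = vapply(attempts, `[[`, character(1), "label_forward"),
    label_backward = vapply(attempts, `[[`, character(1), "label_backward"),
    classification = attempt_classifications(attempts),
    n_crossings = vapply(attempts, `[[`, numeric(1), "n_crossings"),
    weight = w,
    duration = vapply(attempts, `[[`, numeric(1), "duration"),
    seed = vapply(attempts, function(a)
      if (is.null(a$seed)) NA_integer_ else as.integer(a$seed), integer(1)))
}

#' Count level crossings of a discretized path
#'
#' Sign changes of `x - level` between consecutive frames (exact zeros are
#' skipped); used to assert the odd-crossing parity of transition paths.
#'
#' @param x coordinate series.
#' @param level the crossing level.
#' @return integer crossing count.
#' @export
count_level_crossings <- function(x, level) {
  s <- sign(x - level)
  s <- s[s != 0]
  sum(diff(s) != 0)
}
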