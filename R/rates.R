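#' Recrossing-corrected path weight
#'
#' Shooting from a dividing surface oversamples trajectories that recross
#' the surface often (each crossing is one more chance for the frame to be
#' selected). The correction weights every attempt by the reciprocal of
#' the summed reciprocal crossing speeds,
#' `w_i proportional to (sum_i 1/|v_i|)^(-1)`:
#' a path crossing once at speed `v` gets weight proportional to `v`; two
#' crossings at speed `v` halve it.
#'
#' The summed reciprocal speeds are measured as the occupation time of a
#' narrow band around the dividing surface divided by the band width (each
#' band transit at speed `v` contributes `1/|v|`); see [shoot_pair()].
#'
#' @param attempt a `shooting_attempt`.
#' @return the unnormalized weight; `NA` (with a warning) when the
#'   recorded surface occupation is zero (an effectively infinite crossing
#'   speed: the attempt is flagged and excluded).
#' @export
path_weight <- function(attempt) {
  s <- attempt$inv_speed_sum
  if (is.null(s) || !length(s))
    stop("weight undefined: attempt has no crossing record")
  if (s == 0) {
    warning("zero surface occupation recorded; attempt flagged and excluded")
    return(NA_real_)
  }
  1 / s
}

#' @rdname path_weight
#' @param attempts a `shooting_ensemble`.
#' @param normalize if `TRUE` (default) the defined weights sum to 1.
#' @return for `path_weights`, a numeric vector aligned with `attempts`
#'   (`NA` for attempts with no crossing or a zero-speed crossing).
#' @export
path_weights <- function(attempts, normalize = TRUE) {
  w <- vapply(attempts, function(a) {
    if (is.null(a$inv_speed_sum) || a$inv_speed_sum == 0) return(NA_real_)
    1 / a$inv_speed_sum
  }, numeric(1))
  if (normalize && any(!is.na(w))) w <- w / sum(w, na.rm = TRUE)
  w
}

#' Binding and unbinding rates from a shooting ensemble
#'
#' Reactive-flux estimator for dividing-surface shooting: with
#' `theta_TP = 1` for transition paths and 0 otherwise, twice the
#' two-state flux equals the equilibrium density at the surface times the
#' shooting average of the recrossing-corrected indicator,
#'
#' `2 (k_b^-1 + k_u^-1)^-1 = p_eq(X_dagger) * < theta_TP (sum_i |v_i|^-1)^-1 >`
#'
#' (the average runs over classified shooting attempts; the factor was
#' validated against brute-force transition counting on analytic
#' benchmarks - see the package tests). The one-way flux
#' `J = k_b p_unbound = k_u p_bound` is then split with the equilibrium
#' constant from integrating the PMF, so that `k_b / k_u = K_eq` holds by
#' construction.
#'
#' Incomplete (timed-out) attempts are excluded from the average: the
#' estimator is defined over classified attempts. Their number is
#' reported so the sensitivity of the rates to this choice can be judged.
#'
#' @param attempts a `shooting_ensemble`.
#' @param p_eq_at_surface equilibrium probability density at the dividing
#'   surface (per CV unit), normalized on the same two-state domain as
#'   `K_eq`.
#' @param K_eq equilibrium constant `P(bound) / P(unbound)`.
#' @param n_boot bootstrap resamples over attempts for the standard
#'   errors.
#' @return object of class `kinetics_result` with `k_b`, `k_u`, `ratio`
#'   (= `K_eq`), the flux `J`, `p_eq`, the shooting average, bootstrap
#'   `se_k_b`/`se_k_u`, and attempt bookkeeping.
#' @export
rates_from_shooting <- function(attempts, p_eq_at_surface, K_eq,
                                n_boot = 1000L) {
  stopifnot(p_eq_at_surface > 0, K_eq > 0)
  cls <- attempt_classifications(attempts)
  use <- which(cls %in% c("TP", "non-TP"))
  if (!any(cls == "TP")) stop("no reactive events in the shooting ensemble")
  term <- vapply(attempts[use], function(a) {
    if (a$classification != "TP") return(0)
    if (is.null(a$inv_speed_sum) || a$inv_speed_sum == 0) return(NA_real_)
    1 / a$inv_speed_sum
  }, numeric(1))
  term <- term[!is.na(term)]
  avg <- mean(term)
  J <- 0.5 * p_eq_at_surface * avg
  p_u <- 1 / (1 + K_eq)
  p_b <- K_eq / (1 + K_eq)
  k_b <- J / p_u
  k_u <- J / p_b
  boot <- replicate(n_boot, {
    Jb <- 0.5 * p_eq_at_surface * mean(sample(term, replace = TRUE))
    c(Jb / p_u, Jb / p_b)
  })
  structure(list(k_b = k_b, k_u = k_u, ratio = k_b / k_u, J = J,
                 p_eq = p_eq_at_surface, K_eq = K_eq,
                 shooting_average = avg,
                 se_k_b = stats::sd(boot[1, ]), se_k_u = stats::sd(boot[2, ]),
                 n_tp = sum(cls == "TP"), n_classified = length(use),
                 n_incomplete = sum(cls == "incomplete"),
                 unit = "1/time (reduced units)"),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("<kinetics_result>\n")
  cat(sprintf("  k_b = %.4g +/- %.2g, k_u = %.4g +/- %.2g  [%s]\n",
              x$k_b, x$se_k_b, x$k_u, x$se_k_u, x$unit))
  cat(sprintf("  flux J = %.4g, K_eq = %.4g, p_eq(X+) = %.4g\n",
              x$J, x$K_eq, x$p_eq))
  cat(sprintf("  %d TP / %d classified (%d incomplete excluded)\n",
              x$n_tp, x$n_classified, x$n_incomplete))
  invisible(x)
}

#' Convert a unimolecular on-rate to a bimolecular rate
#'
#' Divides the unimolecular association rate by the two-dimensional
#' concentration of partner peptides in the bilayer,
#' `c = (n_peptides - 1) / (n_lipids_per_leaflet * area_per_lipid)`,
#' using 0.76 nm^2 per POPC lipid by default. The conventions (partner
#' count `n - 1`, per-leaflet lipid count setting the patch area) are
#' arguments, not constants.
#'
#' @param k_on unimolecular association rate (1/s or 1/time).
#' @param n_peptides peptides in the patch (>= 2).
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param area_per_lipid nm^2 per lipid.
#' @return bimolecular rate, molecule^-1 nm^2 per unit time.
#' @export
to_bimolecular <- function(k_on, n_peptides, n_lipids_per_leaflet,
                           area_per_lipid = area_per_popc()) {
  stopifnot(n_peptides >= 2, n_lipids_per_leaflet > 0)
  if (area_per_lipid <= 0) stop("area per lipid must be positive")
  area <- n_lipids_per_leaflet * area_per_lipid
  conc <- (n_peptides - 1) / area
  k_on / conc
}

#' Stability-corrected off rate
#'
#' When the simulated binding stability differs from experiment, and the
#' whole difference in the dissociation constant is attributed to the off
#' rate, the simulated off rate is rescaled by the stability mismatch:
#' `k_off_corrected = k_off_sim * exp(-(dG_exp - dG_sim) / kT)`,
#' with binding stabilities in k_B T (more positive = more stable). The
#' corrected `k_off / k_on` then reproduces the experimental K_d.
#'
#' @param k_off_sim simulated off rate.
#' @param delta_G_sim,delta_G_exp binding stabilities (k_B T).
#' @return corrected off rate (same units as `k_off_sim`).
#' @export
corrected_off_rate <- function(k_off_sim, delta_G_sim, delta_G_exp) {
  stopifnot(is.finite(delta_G_sim), is.finite(delta_G_exp))
  k_off_sim * exp(-(delta_G_exp - delta_G_sim))
}

#' Physical constants used in unit conversions
#'
#' `area_per_popc()`: lateral area per POPC lipid in a fluid bilayer
#' (nm^2). `lipid_diffusion_popc()`: lateral self-diffusion coefficient
#' of POPC in a pure bilayer (cm^2/s). `peptide_diffusion_water()`:
#' translational diffusion coefficient of a peptide of comparable
#' molecular weight in water (cm^2/s). The ratio of the last two is the
#' viscosity contrast that makes membrane association so much slower than
#' association in solution (mean-square displacement in any direction
#' scales with D, so the contrast exceeds 50-fold).
#'
#' @return numeric scalar.
#' @export
area_per_popc <- function() 0.76

#' @rdname area_per_popc
#' @export
lipid_diffusion_popc <- function() 5e-8

#' @rdname area_per_popc
#' @export
peptide_diffusion_water <- function() 3e-6
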