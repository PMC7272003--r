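#' Brownian-dynamics toy helix dimer
#'
#' A minimal two-rod stand-in for a transmembrane helix dimer: each "helix"
#' is a rigid rod of `n_beads` beads (one bead per residue) whose centre
#' moves in the membrane plane, with one in-plane rotation and one tilt
#' angle per rod (the tilt is restrained harmonically by the membrane).
#' Beads of different rods repel below a core distance and attract through
#' Gaussian wells centred at the contact distance `r_contact`. The
#' nonspecific amplitude of pair (i, j) is `eps_nonspecific * g_i * g_j`
#' with `g_k = (k / n_beads)^cterm_exponent` growing towards the
#' C-terminus (bead `n_beads`); designated native pairs get an extra,
#' *narrower* well of depth `eps_native`. The widths mirror real helix
#' interfaces: specific (native) interactions are short-ranged
#' (`w_att_native`), nonspecific packing is broad (`w_att`), so docked
#' rods slide between registries almost freely while locking into the
#' native registry costs a distinct barrier.
#'
#' The default native interface is the shifted registry `(i, i+1)`,
#' `i = 3..8`. Because the nonspecific attraction is maximal for the
#' in-register alignment `(i, i)` (a diagonal sum of the per-bead
#' weights always beats a shifted one), the model has, by construction,
#' a bound intermediate distinct from the native dimer: rods first dock
#' in register through nonspecific, C-terminally weighted contacts (the
#' encounter complex I), and must slide by one bead spacing - breaking
#' those contacts while forming the native ones - to reach the native
#' state B. Native contacts therefore gate the I -> B transition, while
#' nonspecific C-terminal contacts drive U -> I, mirroring the two-step
#' association mechanism the package is built to analyse.
#'
#' Reduced units: lengths in "nm" (bead diameter 0.5 nm, so CV magnitudes
#' are in the range familiar from real helix dimers), energies in k_B T,
#' and times in units set by the diffusion coefficients.
#'
#' @param n_beads beads (residues) per rod.
#' @param spacing bead spacing along the rod axis, nm.
#' @param box side of the periodic membrane patch, nm.
#' @param bead_diameter nominal bead diameter, nm (sets the overlap-retry
#'   threshold at 5% of it).
#' @param native_pairs two-column integer matrix of native-interface bead
#'   pairs (chain A bead, chain B bead); must be a strict subset of all
#'   pairs. Default: in-register pairs 3..8.
#' @param eps_native extra attraction of each native pair, k_B T.
#' @param eps_nonspecific scale of the nonspecific attraction, k_B T.
#' @param cterm_exponent exponent of the C-terminal weighting `g_k`.
#' @param r_contact centre of the attraction wells, nm.
#' @param w_att width of the nonspecific attraction well, nm.
#' @param w_att_native width of the native attraction well, nm.
#' @param k_rep core repulsion stiffness, k_B T / nm^2 below `sig_rep`.
#' @param sig_rep core repulsion onset distance, nm.
#' @param k_tilt tilt restraint stiffness, k_B T / rad^2.
#' @param D_trans,D_rot translational (nm^2/time) and rotational
#'   (rad^2/time) diffusion coefficients.
#' @param anchor_lo,anchor_hi bead indices anchoring the crossing
#'   pseudo-dihedral (A_lo, A_hi, B_hi, B_lo).
#' @return object of class `toy_dimer_model`.
#' @export
toy_dimer_model <- function(n_beads = 10L, spacing = 0.5, box = 6,
                            bead_diameter = 0.5,
                            native_pairs = cbind(3:8, 4:9),
                            eps_native = 0.8, eps_nonspecific = 4.2,
                            cterm_exponent = 6, r_contact = 0.38,
                            w_att = 0.05, w_att_native = 0.05,
                            k_rep = 200, sig_rep = 0.35,
                            k_tilt = 20, D_trans = 0.5, D_rot = 0.3,
                            anchor_lo = 2L, anchor_hi = 9L) {
  n_beads <- as.integer(n_beads)
  native_pairs <- matrix(as.integer(native_pairs), ncol = 2L)
  stopifnot(n_beads >= 4L, all(native_pairs >= 1L),
            all(native_pairs <= n_beads),
            nrow(native_pairs) >= 1L, nrow(native_pairs) < n_beads^2,
            anchor_lo >= 1L, anchor_hi <= n_beads, anchor_lo < anchor_hi)
  if (anyDuplicated(native_pairs))
    stop("duplicate native pairs")
  g <- (seq_len(n_beads) / n_beads)^cterm_exponent
  amp <- eps_nonspecific * outer(g, g)
  amp_nat <- matrix(0, n_beads, n_beads)
  amp_nat[native_pairs] <- eps_native
  structure(list(
    n_beads = n_beads, spacing = spacing, box = box,
    bead_diameter = bead_diameter, native_pairs = native_pairs,
    eps_native = eps_native, eps_nonspecific = eps_nonspecific,
    cterm_exponent = cterm_exponent, g = g, amp = amp, amp_nat = amp_nat,
    r_contact = r_contact, w_att = w_att, w_att_native = w_att_native,
    k_rep = k_rep, sig_rep = sig_rep,
    k_tilt = k_tilt, D_trans = D_trans, D_rot = D_rot,
    anchor_lo = as.integer(anchor_lo), anchor_hi = as.integer(anchor_hi)),
    class = "toy_dimer_model")
}

#' @export
print.toy_dimer_model <- function(x, ...) {
  cat("<toy_dimer_model>", x$n_beads, "beads/rod, box", x$box, "nm,",
      nrow(x$native_pairs), "native pairs\n")
  cat("  eps_native", x$eps_native, "k_BT; eps_nonspecific",
      x$eps_nonspecific, "k_BT (C-terminal exponent", x$cterm_exponent,
      ")\n")
  invisible(x)
}

# parameter list handed to the C++ propagator
dimer_cpp_par <- function(model, params) {
  list(n_beads = model$n_beads, spacing = model$spacing, box = model$box,
       k_rep = model$k_rep, sig_rep = model$sig_rep,
       r_att = model$r_contact, w_att = model$w_att,
       w_att_nat = model$w_att_native, k_tilt = model$k_tilt,
       D_trans = model$D_trans, D_rot = model$D_rot,
       kT = params$kT, dt = params$dt,
       d_min = 0.05 * model$bead_diameter,
       amp = model$amp, amp_nat = model$amp_nat,
       drms_i = as.integer(model$native_pairs[, 1]),
       drms_j = as.integer(model$native_pairs[, 2]),
       drms_r0 = rep(model$r_contact, nrow(model$native_pairs)),
       anchor_lo = model$anchor_lo, anchor_hi = model$anchor_hi)
}

#' Reference states of the toy dimer
#'
#' `dimer_native_state()`: rods parallel in the native registry (chain B
#' shifted along the axis so every designated native pair sits at the
#' contact distance; D_RMS = 0 there by construction).
#' `dimer_intermediate_state()`: the in-register nonspecific dock (the
#' encounter complex I). `dimer_separate_state()`: rods half a box apart
#' (unbound). The state vector is `(xA, yA, phiA, psiA, xB, yB, phiB,
#' psiB)`.
#'
#' @param model a [toy_dimer_model()].
#' @return numeric length-8 state vector.
#' @export
dimer_native_state <- function(model) {
  shift <- (mean(model$native_pairs[, 1]) - mean(model$native_pairs[, 2])) *
    model$spacing
  c(0, 0, 0, 0, shift, model$r_contact, 0, 0)
}

#' @rdname dimer_native_state
#' @export
dimer_intermediate_state <- function(model) {
  c(0, 0, 0, 0, 0, model$r_contact, 0, 0)
}

#' @rdname dimer_native_state
#' @export
dimer_separate_state <- function(model) {
  c(0, 0, 0, 0, 0, model$box / 2, 0, 0)
}

#' Convert a dimer state to a labelled conformation
#'
#' Beads become C-alpha pseudo-atoms (one per residue) of chains "A" and
#' "B", so the generic CV and contact code applies unchanged. Chain B is
#' translated to the periodic image nearest chain A, matching the
#' propagator's convention.
#'
#' @param model a [toy_dimer_model()].
#' @param state length-8 state vector.
#' @return a [conformation()].
#' @export
dimer_conformation <- function(model, state) {
  par <- dimer_cpp_par(model, langevin_params(dt = 1e-5))
  xyz <- dimer_coords_cpp(par, as.numeric(state))
  n <- model$n_beads
  conformation(chain = rep(c("A", "B"), each = n),
               resid = rep(seq_len(n), 2L), name = "CA",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Native conformation and native contact set of a toy dimer
#'
#' @param model a [toy_dimer_model()].
#' @param residue_range,build_cutoff passed to [build_native_set()];
#'   defaults restrict to the native-interface bead range.
#' @return `dimer_native_conformation()`: a [conformation()];
#'   `dimer_native_set()`: a `native_contact_set`.
#' @export
dimer_native_conformation <- function(model) {
  dimer_conformation(model, dimer_native_state(model))
}

#' @rdname dimer_native_conformation
#' @export
dimer_native_set <- function(model, residue_range = NULL,
                             build_cutoff = 0.6) {
  if (is.null(residue_range))
    residue_range <- range(model$native_pairs)
  build_native_set(dimer_native_conformation(model), residue_range,
                   build_cutoff)
}

#' Anchor table for the toy dimer crossing angle
#'
#' @param model a [toy_dimer_model()].
#' @return data.frame usable with [crossing_angle()].
#' @export
dimer_anchors <- function(model) {
  data.frame(chain = c("A", "A", "B", "B"),
             resid = c(model$anchor_lo, model$anchor_hi,
                       model$anchor_hi, model$anchor_lo),
             name = "CA")
}

#' Simulate the toy dimer with Brownian dynamics
#'
#' Overdamped rigid-body dynamics of the two rods (translation in the
#' membrane plane, in-plane rotation, restrained tilt). Steps that would
#' bring any bead pair closer than 5% of the bead diameter are rejected
#' and retried with fresh noise. An optional harmonic umbrella bias acts
#' on the D_RMS coordinate defined by the model's native pairs.
#'
#' @param model a [toy_dimer_model()].
#' @param params a [langevin_params()] (its `D` is ignored; the model
#'   carries its own diffusion coefficients).
#' @param n_steps number of BD steps.
#' @param initial length-8 state vector, or `"native"` / `"separate"`.
#' @param thin store every `thin`-th frame.
#' @param bias optional list(center, k): umbrella on D_RMS (nm).
#' @return object of class `dimer_trajectory`: stored `states` (matrix,
#'   one row per frame), per-frame `drms` and `theta`, record interval
#'   `dt`, and the model/params provenance.
#' @export
simulate_toy_dimer <- function(model, params, n_steps, initial = "separate",
                               thin = 10L, bias = NULL) {
  stopifnot(inherits(model, "toy_dimer_model"),
            inherits(params, "langevin_params"))
  if (is.character(initial))
    initial <- switch(match.arg(initial, c("separate", "native")),
                      separate = dimer_separate_state(model),
                      native = dimer_native_state(model))
  if (!is.null(params$seed)) set.seed(params$seed)
  bc <- 0; bk <- 0
  if (!is.null(bias)) { bc <- bias$center; bk <- bias$k }
  par <- dimer_cpp_par(model, params)
  out <- sim_dimer_cpp(par, as.numeric(initial), n_steps, as.integer(thin),
                       bc, bk)
  structure(list(states = out$states, drms = out$drms, theta = out$theta,
                 dt = params$dt * thin, thin = as.integer(thin),
                 n_steps = n_steps, model = model, params = params,
                 bias = bias),
            class = "dimer_trajectory")
}

#' @export
print.dimer_trajectory <- function(x, ...) {
  cat("<dimer_trajectory>", nrow(x$states), "frames, record interval",
      x$dt, "\n")
  invisible(x)
}

#' Hybrid CV series of a dimer trajectory
#'
#' @param traj a [simulate_toy_dimer()] result.
#' @param params a [hybrid_cv_params()].
#' @return numeric X series, one value per stored frame.
#' @export
dimer_x_series <- function(traj, params = hybrid_cv_params()) {
  hybrid_cv(traj$drms, traj$theta, params)
}

#' Per-frame inter-chain contacts of a dimer trajectory
#'
#' @param traj a [simulate_toy_dimer()] result (or a bare state matrix via
#'   `states`).
#' @param cutoff contact cutoff, nm.
#' @param frames optional frame subset (indices into the stored frames).
#' @return logical matrix frames x pairs; column `(i-1)*n + j` is contact
#'   (A_i, B_j). Attribute `pairs` holds the (i, j) index table.
#' @export
dimer_contact_frames <- function(traj, cutoff = 0.45, frames = NULL) {
  st <- traj$states
  if (!is.null(frames)) st <- st[frames, , drop = FALSE]
  par <- dimer_cpp_par(traj$model, traj$params)
  m <- dimer_contacts_cpp(par, st, cutoff)
  n <- traj$model$n_beads
  attr(m, "pairs") <- cbind(i = rep(seq_len(n), each = n),
                            j = rep(seq_len(n), times = n))
  m
}

#' Reference toy dimer parameter set
#'
#' The frozen stated world used throughout the tests: the default
#' [toy_dimer_model()] together with the integration step, the hybrid-CV
#' mixing coefficient, and the landscape constants read off its
#' equilibrium free-energy profile on X. The profile has three populated
#' regions - the native dimer B (X near 0.04), the in-register
#' nonspecific dock I (X near 0.44), and the unbound state U (X above
#' about 1.4) - separated by maxima near X = 0.33 (the native-docking
#' barrier, the "second"/inner barrier) and X = 0.80 (the
#' association barrier, the "first"/outer barrier).
#'
#' @return list with elements `model`, `params`, `mu`, `basins_b2`
#'   (native B vs intermediate I), `basins_b1` (intermediate vs unbound),
#'   `x_dagger_2`, `x_dagger_1` (dividing surfaces), and `u_cut` (the
#'   I/U state boundary used for the two-state restriction of barrier-2
#'   statistics).
#' @export
toy_dimer_reference <- function() {
  model <- toy_dimer_model()
  params <- langevin_params(D = 1, kT = 1, dt = 5e-5)  # D unused: the
  # dimer model carries its own diffusion coefficients
  list(model = model, params = params, mu = 0.1,
       basins_b2 = basin_spec(a = c(-0.5, 0.15), b = c(0.44, 0.60)),
       basins_b1 = basin_spec(a = c(0.36, 0.58), b = c(1.6, 3.4)),
       x_dagger_2 = 0.33, x_dagger_1 = 0.80, u_cut = 0.80)
}
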