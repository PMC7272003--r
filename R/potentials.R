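#' Analytic multi-well test potentials
#'
#' Construct a one-dimensional potential with minima at stated positions and
#' interior maxima of stated heights. Between the stated extrema the potential
#' is a cubic smoothstep with zero slope at every extremum, so the requested
#' wells and barriers are exact stationary points of the analytic form (the
#' gradient vanishes there identically). Beyond the outermost wells a
#' harmonic confinement of stiffness `k_conf` keeps trajectories in the
#' domain. Barrier heights are measured from the higher of the two adjacent
#' minima, so a barrier of height `b` is crossed at cost `b` from either side
#' when the wells are equally deep.
#'
#' @param wells numeric vector of two or more strictly increasing well
#'   positions (coordinate units).
#' @param barrier_heights numeric vector of `length(wells) - 1` positive
#'   barrier heights (units of `k_B T`).
#' @param well_values optional depths of the wells (same units); defaults to
#'   all zero. Recycled to `length(wells)`.
#' @param barrier_positions optional positions of the interior maxima;
#'   defaults to the midpoints between adjacent wells. Must interleave the
#'   wells strictly.
#' @param k_conf stiffness of the harmonic confinement outside the outermost
#'   wells (energy / coordinate unit^2).
#' @return An object of class `potential_model` with analytic value and
#'   gradient (see [potential_value()], [potential_grad()]).
#' @examples
#' V <- triple_well(c(0, 0.4, 1.8), c(4, 6))
#' potential_value(V, c(0, 0.2, 0.4))
#' @export
multi_well_potential <- function(wells, barrier_heights, well_values = 0,
                                 barrier_positions = NULL, k_conf = 100) {
  wells <- as.numeric(wells)
  barrier_heights <- as.numeric(barrier_heights)
  nw <- length(wells)
  if (nw < 2L) stop("need at least two wells")
  if (any(diff(wells) <= 0)) stop("well positions must be strictly increasing")
  if (length(barrier_heights) != nw - 1L)
    stop("need exactly one barrier height per adjacent well pair")
  if (any(barrier_heights <= 0)) stop("barrier heights must be positive")
  well_values <- rep_len(as.numeric(well_values), nw)
  if (is.null(barrier_positions)) {
    barrier_positions <- (wells[-nw] + wells[-1L]) / 2
  } else {
    barrier_positions <- as.numeric(barrier_positions)
    if (length(barrier_positions) != nw - 1L ||
        any(barrier_positions <= wells[-nw]) ||
        any(barrier_positions >= wells[-1L]))
      stop("barrier positions must strictly interleave the wells")
  }
  barrier_values <- pmax(well_values[-nw], well_values[-1L]) + barrier_heights
  knots <- numeric(2L * nw - 1L)
  vals <- numeric(2L * nw - 1L)
  knots[seq(1L, 2L * nw - 1L, by = 2L)] <- wells
  knots[seq(2L, 2L * nw - 2L, by = 2L)] <- barrier_positions
  vals[seq(1L, 2L * nw - 1L, by = 2L)] <- well_values
  vals[seq(2L, 2L * nw - 2L, by = 2L)] <- barrier_values
  structure(
    list(form = "piecewise_cubic", knots = knots, values = vals,
         wells = wells, well_values = well_values,
         barrier_positions = barrier_positions,
         barrier_heights = barrier_heights, k_conf = k_conf,
         domain = range(knots) + c(-1, 1) * 10 * max(diff(range(knots)), 1)),
    class = "potential_model")
}

#' @rdname multi_well_potential
#' @param barriers alias for `barrier_heights` in the three-well constructor.
#' @export
triple_well <- function(wells, barriers, well_values = 0, k_conf = 100) {
  if (length(wells) != 3L) stop("triple_well() needs exactly three wells")
  multi_well_potential(wells, barriers, well_values, k_conf = k_conf)
}

#' @rdname multi_well_potential
#' @param barrier single barrier height for the two-well constructor.
#' @export
double_well <- function(wells, barrier, well_values = 0, k_conf = 100) {
  if (length(wells) != 2L) stop("double_well() needs exactly two wells")
  multi_well_potential(wells, barrier, well_values, k_conf = k_conf)
}

#' Flat (free-diffusion) potential
#'
#' Zero everywhere; trajectories on it are pure Brownian motion with
#' mean-square displacement 2 D t.
#' @export
flat_potential <- function() {
  structure(list(form = "flat", knots = numeric(0), values = numeric(0),
                 k_conf = 0, domain = c(-Inf, Inf)),
            class = "potential_model")
}

#' Evaluate a potential or its gradient
#'
#' @param model a `potential_model`.
#' @param x numeric vector of coordinates.
#' @return numeric vector of energies (`potential_value`) or derivatives
#'   dV/dx (`potential_grad`).
#' @export
potential_value <- function(model, x) {
  stopifnot(inherits(model, "potential_model"))
  piecewise_value_cpp(as.numeric(x), model$knots, model$values, model$k_conf)
}

#' @rdname potential_value
#' @export
potential_grad <- function(model, x) {
  stopifnot(inherits(model, "potential_model"))
  piecewise_grad_cpp(as.numeric(x), model$knots, model$values, model$k_conf)
}

#' @export
print.potential_model <- function(x, ...) {
  cat("<potential_model>", x$form, "\n")
  if (length(x$knots)) {
    cat("  wells at:", paste(signif(x$wells, 4), collapse = ", "), "\n")
    cat("  barriers:", paste(signif(x$barrier_heights, 4), collapse = ", "),
        "k_BT at", paste(signif(x$barrier_positions, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Boltzmann equilibrium density of a 1D potential
#'
#' Numerically normalized density exp(-V(x)/kT) on `[lower, upper]`,
#' evaluated on a fine grid; used as the analytic stationary-density oracle
#' for the Langevin propagator and as the exact `p_eq` in rate benchmarks.
#'
#' @param model a `potential_model`.
#' @param kT thermal energy.
#' @param lower,upper integration domain (defaults to the outer wells padded
#'   by five confinement standard deviations).
#' @param n grid size.
#' @return data.frame with columns `x` and `density` (integrates to 1 by the
#'   trapezoidal rule).
#' @export
boltzmann_density <- function(model, kT = 1, lower = NULL, upper = NULL,
                              n = 4096) {
  stopifnot(inherits(model, "potential_model"))
  if (!length(model$knots)) stop("flat potential has no normalizable density")
  pad <- 5 * sqrt(kT / model$k_conf)
  if (is.null(lower)) lower <- model$knots[1] - pad
  if (is.null(upper)) upper <- model$knots[length(model$knots)] + pad
  x <- seq(lower, upper, length.out = n)
  w <- exp(-(potential_value(model, x) - min(potential_value(model, x))) / kT)
  Z <- trapz(x, w)
  data.frame(x = x, density = w / Z)
}

# trapezoidal quadrature on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
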