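#' Contact probabilities on transition paths, p(q|TP)
#'
#' The average population of every inter-chain residue contact over the
#' transition-path ensemble: frames within one path count uniformly, and
#' paths are combined with the recrossing-corrected weights (see
#' [path_weight()]), which corrects the shooting ensemble's bias towards
#' frequently recrossing trajectories.
#'
#' Two weightings are available. The default (`frame_weighted = FALSE`)
#' is the path-ensemble average: every transition path counts once with
#' its recrossing weight `w_i`, frames uniformly within the path. With
#' `frame_weighted = TRUE` paths additionally count in proportion to
#' their frame number (duration), giving the probability that a random
#' equilibrium *snapshot* on a transition path shows the contact - the
#' quantity that enters the Bayes inversion of [p_tp_given_q()]
#' consistently, since p(TP)_nn and p(q)_nn are snapshot fractions. When
#' contact patterns correlate with path duration the two differ.
#'
#' @param tp_contacts list with one logical matrix (frames x pairs) per
#'   transition path, e.g. from [dimer_contact_frames()] on each TP's
#'   frames.
#' @param weights per-path weights (any positive scale).
#' @param frame_weighted see above.
#' @return numeric vector of per-pair probabilities in `[0, 1]` (named by
#'   the column names of the first matrix, if any).
#' @export
p_q_given_tp <- function(tp_contacts, weights, frame_weighted = FALSE) {
  stopifnot(length(tp_contacts) >= 1L,
            length(weights) == length(tp_contacts), all(weights > 0))
  if (frame_weighted)
    weights <- weights * vapply(tp_contacts, nrow, numeric(1))
  per_path <- vapply(tp_contacts, function(m) colMeans(m),
                     numeric(ncol(tp_contacts[[1]])))
  if (is.null(dim(per_path))) per_path <- matrix(per_path, nrow = 1L)
  as.numeric(per_path %*% weights) / sum(weights)
}

#' Probability of being on a transition path when not bound, p(TP)_nn
#'
#' In steady state each association event contributes one waiting period
#' of mean `1/k_bind` outside the bound state plus two transition-path
#' transits (one binding, one unbinding) of mean duration `tau_TP`, so
#'
#' `p(TP)_nn = 2 tau_TP / (2 tau_TP + 1/k_bind)`.
#'
#' @param tau_tp mean transition-path duration (time units).
#' @param k_bind binding rate (1/time).
#' @return probability in `[0, 1)`.
#' @export
p_tp_nn <- function(tau_tp, k_bind) {
  stopifnot(tau_tp >= 0, k_bind > 0)
  2 * tau_tp / (2 * tau_tp + 1 / k_bind)
}

#' How predictive is a contact of productive binding: p(TP|q)_nn
#'
#' Bayes inversion of the transition-path contact statistics:
#'
#' `p(TP|q_ij)_nn = p(q_ij|TP) * p(TP)_nn / p(q_ij)_nn`
#'
#' where `p(q_ij)_nn` is the equilibrium probability of the contact among
#' non-native (not-bound) configurations, obtained from reweighted
#' umbrella sampling restricted to the non-native states. Cells with
#' `p(q)_nn = 0`, or with fewer than `min_cond` effective conditioning
#' samples, are undefined (`NA`) rather than 0 - this avoids spurious
#' extreme ratios.
#'
#' @param p_q_tp per-pair `p(q|TP)` (from [p_q_given_tp()]).
#' @param p_q_nn per-pair equilibrium contact probability among non-native
#'   frames (same length/order).
#' @param p_tp_nn_value scalar `p(TP)_nn` (from [p_tp_nn()]).
#' @param native_mask logical per-pair flags: is the pair part of the
#'   native interface?
#' @param n_cond optional per-pair effective count of conditioning frames
#'   (non-native frames with the contact formed).
#' @param min_cond minimum-evidence threshold.
#' @param barrier barrier id tag (1 or 2), bookkeeping only.
#' @return object of class `mechanism_maps` with per-pair `p_q_tp`,
#'   `p_q_nn`, `p_tp_q`, `native_mask`, `n_cond`, `barrier`.
#' @export
p_tp_given_q <- function(p_q_tp, p_q_nn, p_tp_nn_value, native_mask,
                         n_cond = NULL, min_cond = 10, barrier = NA) {
  if (length(p_q_tp) != length(p_q_nn))
    stop("p(q|TP) and p(q)_nn have different lengths (",
         length(p_q_tp), " vs ", length(p_q_nn), ")")
  stopifnot(length(native_mask) == length(p_q_tp),
            p_tp_nn_value >= 0, p_tp_nn_value <= 1)
  p <- ifelse(p_q_nn > 0, p_q_tp * p_tp_nn_value / p_q_nn, NA_real_)
  if (!is.null(n_cond)) p[n_cond < min_cond] <- NA_real_
  structure(list(p_q_tp = p_q_tp, p_q_nn = p_q_nn, p_tp_q = p,
                 p_tp_nn = p_tp_nn_value,
                 native_mask = as.logical(native_mask),
                 n_cond = n_cond, barrier = barrier),
            class = "mechanism_maps")
}

#' @export
print.mechanism_maps <- function(x, ...) {
  ok <- !is.na(x$p_tp_q)
  cat("<mechanism_maps> barrier", x$barrier, "-", sum(ok), "defined pairs",
      "(", sum(x$native_mask), "native )\n")
  if (any(ok))
    cat("  p(TP|q)_nn range:", signif(range(x$p_tp_q[ok]), 3),
        "; p(TP)_nn =", signif(x$p_tp_nn, 3), "\n")
  invisible(x)
}

#' Tail distributions of p(TP|q)_nn by contact class
#'
#' For each threshold, the number of native and of non-native contacts
#' whose `p(TP|q)_nn` strictly exceeds it: two monotone non-increasing
#' counting curves that summarize whether native or non-native contacts
#' carry the predictive signal for a barrier crossing.
#'
#' @param maps a `mechanism_maps`.
#' @param thresholds numeric thresholds in `[0, 1]`.
#' @return data.frame with `threshold`, `n_native`, `n_nonnative`.
#' @export
tail_distribution <- function(maps, thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(maps, "mechanism_maps"),
            all(thresholds >= 0), all(thresholds <= 1))
  p <- maps$p_tp_q
  ok <- !is.na(p)
  data.frame(
    threshold = thresholds,
    n_native = vapply(thresholds, function(th)
      sum(ok & maps$native_mask & p > th), numeric(1)),
    n_nonnative = vapply(thresholds, function(th)
      sum(ok & !maps$native_mask & p > th), numeric(1)))
}

#' Weighted equilibrium contact probabilities
#'
#' Per-pair probability of a contact over a set of frames with (WHAM or
#' uniform) frame weights; with the frames restricted to the non-native
#' conditioning set this is `p(q)_nn`. Also returns the effective number
#' of conditioning frames per pair, `n_cond = (sum w | q)^2 / (sum w^2 | q)`,
#' used for the minimum-evidence mask.
#'
#' @param contacts logical matrix, frames x pairs.
#' @param weights per-frame weights (default uniform).
#' @return list with `p` (per-pair probability) and `n_cond`.
#' @export
contact_probability <- function(contacts, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(contacts))
  stopifnot(length(weights) == nrow(contacts))
  w <- weights / sum(weights)
  p <- as.numeric(crossprod(contacts, w))
  wsum <- as.numeric(crossprod(contacts, w))
  w2sum <- as.numeric(crossprod(contacts, w^2))
  n_cond <- ifelse(w2sum > 0, wsum^2 / w2sum, 0)
  list(p = p, n_cond = n_cond)
}

#' Directly counted p(TP|q)_nn from an equilibrium trajectory
#'
#' The brute-force oracle for the Bayes reconstruction: over the
#' non-native frames of a long unbiased run, condition on each contact
#' being formed and count the fraction of those frames that lie on a
#' transition path.
#'
#' @param contacts logical matrix (non-native frames x pairs).
#' @param tp_flag logical per-frame: does the frame lie on a transition
#'   path?
#' @return list with `p` (per-pair conditional probability, `NA` where
#'   the contact never forms), `n_cond` (conditioning frame counts) and
#'   `p_tp_nn` (the unconditioned fraction).
#' @export
direct_p_tp_given_q <- function(contacts, tp_flag) {
  stopifnot(nrow(contacts) == length(tp_flag))
  n_cond <- colSums(contacts)
  n_tp <- as.numeric(crossprod(contacts, tp_flag))
  list(p = ifelse(n_cond > 0, n_tp / n_cond, NA_real_),
       n_cond = n_cond,
       p_tp_nn = mean(tp_flag))
}

#' Frames of the non-native conditioning set
#'
#' Membership rule for all `_nn` quantities of a two-barrier system: keep
#' frames that are not in the product (bound) basin of the barrier under
#' study, and drop frames in the third state not being considered, so that
#' each barrier is treated as a two-state problem. Frames in the excluded
#' state never contribute to any `_nn` average.
#'
#' @param x reaction-coordinate series.
#' @param bound_interval `c(lo, hi)` of the product basin to exclude.
#' @param exclude_interval optional `c(lo, hi)` of the third state to
#'   exclude (e.g. the unbound region when studying the intermediate ->
#'   native barrier).
#' @return logical per-frame membership vector.
#' @export
nn_frames <- function(x, bound_interval, exclude_interval = NULL) {
  keep <- !(x >= bound_interval[1] & x <= bound_interval[2])
  if (!is.null(exclude_interval))
    keep <- keep & !(x >= exclude_interval[1] & x <= exclude_interval[2])
  keep
}

#' Write mechanism maps as tidy and matrix tables
#'
#' Writes a long-format table (i, j, native flag, p(q|TP), p(q)_nn,
#' p(TP|q)_nn) and, when the pair index table is supplied, square
#' matrices of each map.
#'
#' @param maps a `mechanism_maps`.
#' @param pairs two-column matrix of (i, j) residue indices per pair.
#' @param path output file (tidy table); matrix files get suffixes.
#' @export
write_mechanism_maps <- function(maps, pairs, path) {
  df <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   native = maps$native_mask,
                   p_q_tp = maps$p_q_tp, p_q_nn = maps$p_q_nn,
                   p_tp_q = maps$p_tp_q)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
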