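#' Umbrella-sampling window
#'
#' One biased simulation window: a harmonic bias `0.5 k (cv - center)^2`
#' on the biasing coordinate, the sampled series of that coordinate, and
#' optionally aligned series of other coordinates computed on the same
#' frames (used for projections).
#'
#' @param center bias centre (CV units).
#' @param k force constant (energy / CV-unit^2); `k = 0` is an unbiased
#'   window.
#' @param cv numeric series of the biased coordinate, one value per frame.
#' @param aux optional named list of aligned auxiliary CV series.
#' @param id window identifier.
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, cv, aux = NULL, id = NULL) {
  stopifnot(k >= 0, length(cv) >= 1L)
  if (!is.null(aux))
    stopifnot(all(vapply(aux, length, 1L) == length(cv)))
  structure(list(center = center, k = k, cv = as.numeric(cv), aux = aux,
                 id = id), class = "umbrella_window")
}

#' Histogram bin specification
#'
#' @param lo,hi domain limits.
#' @param width bin width (default 0.02, matching the scale of the
#'   0.005 frame-selection tolerance used at the dividing surfaces).
#' @return object of class `bin_spec` with element `edges`.
#' @export
bin_spec <- function(lo, hi, width = 0.02) {
  stopifnot(hi > lo, width > 0)
  n <- ceiling((hi - lo) / width)
  structure(list(lo = lo, hi = lo + n * width, width = width,
                 edges = lo + (0:n) * width,
                 mids = lo + ((1:n) - 0.5) * width),
            class = "bin_spec")
}

#' Weighted histogram analysis of umbrella windows
#'
#' Recovers the unbiased free-energy profile from a set of harmonically
#' biased windows by direct iteration of the WHAM equations (binned), then
#' computes per-frame unbiasing weights from the converged window free
#' energies. The per-frame weights allow the PMF to be projected onto any
#' coordinate computed on the same frames (see [project_pmf()]).
#'
#' Windows from independent runs (e.g. started from bound and from unbound
#' configurations) are pooled by simply passing them together; WHAM assigns
#' each its own free-energy offset.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param bins a [bin_spec()] covering the sampled range of the bias CV.
#' @param kT thermal energy (energies are in k_B T by default).
#' @param tol convergence tolerance on the window free energies.
#' @param max_iter iteration cap.
#' @param min_overlap adjacent-window histogram overlap (overlap
#'   coefficient) below which a warning is issued; zero overlap is an
#'   error.
#' @return object of class `wham_fit`: the 1D `pmf` on the bias CV, window
#'   free energies `f` (k_B T), normalized per-frame `weights` (one entry
#'   per frame of the concatenated windows, summing to 1), the frame
#'   bookkeeping `frame_window`, and the convergence record.
#' @export
wham <- function(windows, bins, kT = 1, tol = 1e-7, max_iter = 100000L,
                 min_overlap = 0.05) {
  stopifnot(length(windows) >= 1L, inherits(bins, "bin_spec"))
  S <- length(windows)
  check_window_overlap(windows, min_overlap)
  mids <- bins$mids
  M <- length(mids)
  counts <- vapply(windows, function(w)
    tabulate_bins(w$cv, bins), numeric(M))     # M x S
  N <- colSums(counts)
  if (any(N == 0)) stop("window with no frames inside the binning domain")
  Mtot <- rowSums(counts)
  # bias Boltzmann factors at bin centres
  C <- vapply(windows, function(w)
    exp(-0.5 * w$k * (mids - w$center)^2 / kT), numeric(M))  # M x S
  g <- rep(1, S)                                # g_i = exp(f_i / kT)
  p <- Mtot / sum(Mtot)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(C %*% (N * g))          # length M
    p <- ifelse(denom > 0, Mtot / denom, 0)
    p <- p / sum(p)
    g_new <- 1 / as.numeric(crossprod(C, p))    # length S
    delta <- max(abs(log(g_new) - log(g)))
    g <- g_new
    if (delta < tol || iter >= max_iter) break
  }
  if (iter >= max_iter)
    warning("WHAM did not reach tolerance ", tol, " in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")")
  # unbinned per-frame weights from the converged offsets
  allcv <- unlist(lapply(windows, `[[`, "cv"))
  frame_window <- rep(seq_len(S), vapply(windows, function(w)
    length(w$cv), 1L))
  denom_t <- rep(0, length(allcv))
  for (i in seq_len(S)) {
    u <- 0.5 * windows[[i]]$k * (allcv - windows[[i]]$center)^2 / kT
    denom_t <- denom_t + N[i] * g[i] * exp(-u)
  }
  w_t <- 1 / denom_t
  w_t <- w_t / sum(w_t)
  pmf <- project_pmf(w_t, allcv, bins, kT = kT)
  structure(list(pmf = pmf, f = kT * log(g), weights = w_t,
                 frame_window = frame_window, cv = allcv, kT = kT,
                 iterations = iter, residual = delta, windows = windows),
            class = "wham_fit")
}

tabulate_bins <- function(x, bins) {
  idx <- findInterval(x, bins$edges, rightmost.closed = TRUE)
  tabulate(idx[idx >= 1L & idx <= length(bins$mids)],
           nbins = length(bins$mids))
}

check_window_overlap <- function(windows, min_overlap) {
  S <- length(windows)
  if (S < 2L) return(invisible())
  biased <- which(vapply(windows, function(w) w$k > 0, TRUE))
  if (length(biased) < 2L) return(invisible())
  ord <- biased[order(vapply(windows[biased], `[[`, 1, "center"))]
  rng <- range(unlist(lapply(windows, `[[`, "cv")))
  bb <- bin_spec(rng[1] - 1e-9, rng[2] + 1e-9,
                 width = max((rng[2] - rng[1]) / 200, 1e-9))
  H <- vapply(windows, function(w) {
    h <- tabulate_bins(w$cv, bb); h / sum(h)
  }, numeric(length(bb$mids)))
  for (k in seq_len(length(ord) - 1L)) {
    i <- ord[k]; j <- ord[k + 1L]
    ov <- sum(pmin(H[, i], H[, j]))
    if (ov == 0)
      stop(sprintf(paste0("non-overlapping adjacent windows: centres %g and ",
                          "%g leave a sampling gap"),
                   windows[[i]]$center, windows[[j]]$center))
    if (ov < min_overlap)
      warning(sprintf("adjacent windows at %g and %g overlap by only %.1f%%",
                      windows[[i]]$center, windows[[j]]$center, 100 * ov))
  }
  invisible()
}

#' @export
print.wham_fit <- function(x, ...) {
  cat("<wham_fit>", length(x$windows), "windows,", length(x$weights),
      "frames; converged to", signif(x$residual, 3), "in", x$iterations,
      "iterations\n")
  invisible(x)
}

# --- PMF container ---------------------------------------------------------

new_pmf <- function(bins_list, density_list, kT, n_eff = NULL) {
  dim <- length(bins_list)
  if (dim == 1L) {
    dens <- density_list[[1]]
    F <- -kT * log(dens)
    F <- F - min(F[is.finite(F)])
  } else {
    dens <- density_list[[1]]
    F <- -kT * log(dens)
    F <- F - min(F[is.finite(F)])
  }
  structure(list(dim = dim, bins = bins_list, density = dens, F = F,
                 kT = kT, n_eff = n_eff), class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  cat("<pmf>", x$dim, "D,",
      paste(vapply(x$bins, function(b) length(b$mids), 1L), collapse = " x "),
      "bins; min F = 0 (anchored)\n")
  invisible(x)
}

#' Project unbiased weights onto one or two coordinates
#'
#' Builds a reweighted PMF on any coordinate(s) computed on the same frames
#' that produced the WHAM weights; this is how hidden barriers are found
#' (e.g. projecting a D_RMS-biased run onto the crossing angle, or onto
#' the hybrid coordinate X).
#'
#' @param weights per-frame unbiasing weights (from [wham()]); need not be
#'   normalized.
#' @param cv1 coordinate series aligned with the weights.
#' @param bins1 a [bin_spec()] for `cv1`.
#' @param cv2,bins2 optional second coordinate for a 2D projection.
#' @param kT thermal energy.
#' @return a `pmf` (1D or 2D). The reweighted density integrates to 1 over
#'   the binned domain; bins also carry the effective sample count
#'   `n_eff = (sum w)^2 / sum w^2`.
#' @export
project_pmf <- function(weights, cv1, bins1, cv2 = NULL, bins2 = NULL,
                        kT = 1) {
  if (length(weights) != length(cv1))
    stop("weights and cv1 have different lengths (",
         length(weights), " vs ", length(cv1), ")")
  w <- weights / sum(weights)
  i1 <- findInterval(cv1, bins1$edges, rightmost.closed = TRUE)
  ok1 <- i1 >= 1L & i1 <= length(bins1$mids)
  if (is.null(cv2)) {
    wsum <- vapply(seq_along(bins1$mids), function(j)
      sum(w[ok1 & i1 == j]), numeric(1))
    w2sum <- vapply(seq_along(bins1$mids), function(j)
      sum(w[ok1 & i1 == j]^2), numeric(1))
    tot <- sum(wsum)
    dens <- wsum / tot / bins1$width
    n_eff <- ifelse(w2sum > 0, wsum^2 / w2sum, 0)
    return(new_pmf(list(bins1), list(dens), kT, n_eff = n_eff))
  }
  if (length(cv2) != length(cv1)) stop("cv2 length mismatch")
  i2 <- findInterval(cv2, bins2$edges, rightmost.closed = TRUE)
  ok <- ok1 & i2 >= 1L & i2 <= length(bins2$mids)
  M1 <- length(bins1$mids); M2 <- length(bins2$mids)
  wsum <- matrix(0, M1, M2)
  agg <- tapply(w[ok], list(factor(i1[ok], levels = 1:M1),
                            factor(i2[ok], levels = 1:M2)), sum)
  wsum[] <- ifelse(is.na(agg), 0, agg)
  tot <- sum(wsum)
  dens <- wsum / tot / (bins1$width * bins2$width)
  new_pmf(list(bins1, bins2), list(dens), kT)
}

#' Locate interior free-energy barriers of a 1D PMF
#'
#' Applies a 3-bin moving-average smoothing to F before the extremum
#' search (single-bin noise maxima are ignored); positions are reported on
#' the unsmoothed grid. The height of each barrier is measured from the
#' lower (deeper) of the two adjacent minima.
#'
#' @param pmf a 1D `pmf`.
#' @param smooth_bins moving-average width (odd; 1 disables smoothing).
#' @param min_n_eff bins with fewer effective samples than this are
#'   ignored (a bin dominated by one or two high-weight frames is not
#'   evidence of a barrier).
#' @return data.frame with `position`, `height`, `index`, ordered by
#'   position; zero rows when F is monotone.
#' @export
locate_barriers <- function(pmf, smooth_bins = 3L, min_n_eff = 0) {
  stopifnot(inherits(pmf, "pmf"), pmf$dim == 1L)
  mids <- pmf$bins[[1]]$mids
  if (length(mids) < 3L) stop("need at least 3 bins")
  Fv <- pmf$F
  if (min_n_eff > 0 && !is.null(pmf$n_eff))
    Fv[pmf$n_eff < min_n_eff] <- Inf
  fin <- which(is.finite(Fv))
  if (length(fin) < 3L) return(data.frame(position = numeric(0),
                                          height = numeric(0),
                                          index = integer(0)))
  # longest contiguous finite stretch
  r <- rle(is.finite(Fv))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  best <- which(r$values)[which.max(r$lengths[r$values])]
  seg <- starts[best]:ends[best]
  Fs <- smooth_ma(Fv[seg], smooth_bins)
  n <- length(seg)
  out <- data.frame(position = numeric(0), height = numeric(0),
                    index = integer(0))
  if (n < 3L) return(out)
  maxima <- which(c(FALSE, Fs[2:(n - 1)] > Fs[1:(n - 2)] &
                           Fs[2:(n - 1)] > Fs[3:n], FALSE))
  for (m in seq_along(maxima)) {
    k <- maxima[m]
    lo <- if (m == 1L) 1L else maxima[m - 1L]
    hi <- if (m == length(maxima)) n else maxima[m + 1L]
    left <- min(Fs[lo:(k - 1L)])
    right <- min(Fs[(k + 1L):hi])
    h <- Fs[k] - min(left, right)
    out <- rbind(out, data.frame(position = mids[seg[k]], height = h,
                                 index = seg[k]))
  }
  out
}

smooth_ma <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  out <- x
  h <- (k - 1L) %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Equilibrium constant by integration of the PMF
#'
#' `K_eq = P(bound) / P(unbound)` with the bound state on the low-X side
#' of `dividing_point` (the native complex sits at X near 0). The density
#' of the dividing bin is split linearly.
#'
#' @param pmf a 1D `pmf`.
#' @param dividing_point interior point separating the two states.
#' @return list with `K_eq`, `p_bound`, `p_unbound` (populations sum to 1).
#' @export
equilibrium_constant <- function(pmf, dividing_point) {
  stopifnot(inherits(pmf, "pmf"), pmf$dim == 1L)
  b <- pmf$bins[[1]]
  if (dividing_point <= b$lo || dividing_point >= b$hi)
    stop("dividing point must be interior to the PMF domain")
  mass <- pmf$density * b$width
  frac <- (dividing_point - b$edges[-length(b$edges)]) / b$width
  frac <- pmin(pmax(frac, 0), 1)
  p_low <- sum(mass * frac)
  p_high <- sum(mass * (1 - frac))
  tot <- p_low + p_high
  if (p_low == 0 || p_high == 0)
    stop("one side of the dividing point has no probability mass")
  list(K_eq = p_low / p_high, p_bound = p_low / tot, p_unbound = p_high / tot)
}

#' Equilibrium probability density at the dividing surface
#'
#' Reads the reweighted density at `x` with a 3-bin local average (the
#' density of a single bin at a barrier top is noisy).
#'
#' @param pmf a 1D `pmf`.
#' @param x coordinate value.
#' @param n_bins averaging width (odd).
#' @return density per CV unit.
#' @export
p_eq_at <- function(pmf, x, n_bins = 3L) {
  stopifnot(inherits(pmf, "pmf"), pmf$dim == 1L)
  b <- pmf$bins[[1]]
  j <- findInterval(x, b$edges, rightmost.closed = TRUE)
  if (j < 1L || j > length(b$mids)) stop("x outside the PMF domain")
  h <- (n_bins - 1L) %/% 2L
  idx <- max(1L, j - h):min(length(b$mids), j + h)
  mean(pmf$density[idx])
}

#' Scan the hybrid-CV mixing coefficient
#'
#' For each candidate `mu`, projects the unbiased weights onto
#' `X(mu) = drms + mu * theta` and records the largest interior barrier
#' between the bound and unbound ends of the profile; returns the table
#' and the `mu` maximizing that barrier. Values of `mu` with no interior
#' barrier get height 0 and are flagged.
#'
#' @param weights per-frame unbiasing weights.
#' @param drms_series,theta_series aligned CV series (nm, rad).
#' @param mu_grid candidate coefficients.
#' @param bin_width X bin width.
#' @param kT thermal energy.
#' @param domain optional `c(lo, hi)` restriction of the X binning (frames
#'   outside are dropped); by default the sampled range is used.
#' @param min_n_eff passed to [locate_barriers()].
#' @return list with `table` (data.frame `mu`, `barrier`, `flagged`) and
#'   `mu_opt`.
#' @export
scan_mu <- function(weights, drms_series, theta_series, mu_grid,
                    bin_width = 0.02, kT = 1, domain = NULL,
                    min_n_eff = 0) {
  stopifnot(length(mu_grid) >= 1L)
  res <- lapply(mu_grid, function(mu) {
    x <- drms_series + mu * theta_series
    dom <- if (is.null(domain)) c(min(x) - bin_width, max(x) + bin_width)
           else domain
    bins <- bin_spec(dom[1], dom[2], bin_width)
    pmf <- project_pmf(weights, x, bins, kT = kT)
    bar <- locate_barriers(pmf, min_n_eff = min_n_eff)
    if (nrow(bar) == 0L) c(0, 1) else c(max(bar$height), 0)
  })
  tab <- data.frame(mu = mu_grid,
                    barrier = vapply(res, `[`, numeric(1), 1),
                    flagged = vapply(res, `[`, numeric(1), 2) > 0)
  list(table = tab, mu_opt = tab$mu[which.max(tab$barrier)])
}

#' Block-bootstrap uncertainty of a WHAM free-energy profile
#'
#' Resamples contiguous blocks within every window (default 10 blocks per
#' window; umbrella samples are autocorrelated, so frames cannot be
#' resampled independently) and recomputes the profile.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param bins a [bin_spec()].
#' @param n_boot bootstrap replicates.
#' @param n_blocks contiguous blocks per window.
#' @param kT,tol passed to [wham()].
#' @return list with `F` (matrix bins x replicates, each anchored at its
#'   minimum) and per-bin `se`.
#' @export
wham_bootstrap <- function(windows, bins, n_boot = 50L, n_blocks = 10L,
                           kT = 1, tol = 1e-6) {
  Fmat <- matrix(NA_real_, length(bins$mids), n_boot)
  for (r in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      n <- length(w$cv)
      bl <- split(seq_len(n), pmin(floor((seq_len(n) - 1L) /
                  ceiling(n / n_blocks)) + 1L, n_blocks))
      idx <- unlist(bl[sample.int(length(bl), length(bl), replace = TRUE)],
                    use.names = FALSE)
      umbrella_window(w$center, w$k, w$cv[idx], id = w$id)
    })
    fit <- suppressWarnings(wham(wb, bins, kT = kT, tol = tol))
    Fmat[, r] <- fit$pmf$F
  }
  list(F = Fmat, se = apply(Fmat, 1L, function(z)
    stats::sd(z[is.finite(z)])))
}

#' Write a PMF as a tab-separated table
#'
#' @param pmf a 1D `pmf`.
#' @param path output file.
#' @param se optional per-bin standard errors.
#' @export
write_pmf <- function(pmf, path, se = NULL) {
  stopifnot(pmf$dim == 1L)
  df <- data.frame(x = pmf$bins[[1]]$mids, F = pmf$F,
                   density = pmf$density)
  if (!is.null(se)) df$stderr <- se
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.pmf <- function(x, ..., xlab = "X", ylab = "F (kT)") {
  if (x$dim == 1L) {
    plot(x$bins[[1]]$mids, x$F, type = "l", xlab = xlab, ylab = ylab, ...)
  } else {
    graphics::image(x$bins[[1]]$mids, x$bins[[2]]$mids,
                    pmin(x$F, stats::quantile(x$F[is.finite(x$F)], 0.98)),
                    xlab = xlab, ylab = ylab, ...)
  }
  invisible(x)
}
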