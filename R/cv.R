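#' Build the native contact set of a two-chain complex
#'
#' Collects all intermolecular heavy-atom pairs that are within
#' `build_cutoff` of each other in the native structure and whose residues
#' fall in `residue_range`, recording the native distance of each pair.
#' These pairs and reference distances define the interhelical distance-RMSD
#' coordinate (see [drms()]). The build cutoff is a documented knob: it must
#' exceed the 0.45 nm contact cutoff so the pair list is not degenerate, and
#' defaults to 0.6 nm.
#'
#' @param native a [conformation()] of the native complex.
#' @param residue_range integer length-2 range of residues (inclusive) on
#'   both chains; `NULL` for no restriction.
#' @param build_cutoff pair-inclusion cutoff in nm (strict `<`).
#' @return a `native_contact_set`: data.frame with columns `chain_a`,
#'   `resid_a`, `name_a`, `chain_b`, `resid_b`, `name_b`, `r0` (nm), with
#'   attributes `build_cutoff` and `residue_range`.
#' @export
build_native_set <- function(native, residue_range = NULL,
                             build_cutoff = 0.6) {
  stopifnot(inherits(native, "conformation"))
  ch <- sort(unique(native$chain))
  a <- native[native$chain == ch[1] & native$heavy, , drop = FALSE]
  b <- native[native$chain == ch[2] & native$heavy, , drop = FALSE]
  if (!is.null(residue_range)) {
    a <- a[a$resid >= residue_range[1] & a$resid <= residue_range[2], ]
    b <- b[b$resid >= residue_range[1] & b$resid <= residue_range[2], ]
  }
  if (!nrow(a) || !nrow(b))
    stop("residue range not present on both chains")
  d <- pair_distances(a, b)
  keep <- which(d < build_cutoff, arr.ind = TRUE)
  if (!nrow(keep))
    stop("empty native contact set: no intermolecular heavy-atom pair ",
         "within ", build_cutoff, " nm; the coordinate is undefined")
  out <- data.frame(chain_a = a$chain[keep[, 1]], resid_a = a$resid[keep[, 1]],
                    name_a = a$name[keep[, 1]], chain_b = b$chain[keep[, 2]],
                    resid_b = b$resid[keep[, 2]], name_b = b$name[keep[, 2]],
                    r0 = d[keep], stringsAsFactors = FALSE)
  out <- out[order(out$resid_a, out$name_a, out$resid_b, out$name_b), ]
  rownames(out) <- NULL
  attr(out, "build_cutoff") <- build_cutoff
  attr(out, "residue_range") <- residue_range
  class(out) <- c("native_contact_set", "data.frame")
  out
}

# all pairwise distances between the atoms of two conformation subsets
pair_distances <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

atom_key <- function(chain, resid, name) paste(chain, resid, name, sep = "|")

#' Interhelical distance RMSD
#'
#' Root-mean-square deviation of the native-pair distances from their
#' reference values:
#' `D_RMS = sqrt( mean over native pairs of (r_ij - r_ij0)^2 )`.
#' Zero in the native complex, and well defined (unlike coordinate RMSD)
#' even after all intermolecular contacts are broken.
#'
#' @param conf a [conformation()].
#' @param native_set a [build_native_set()] result.
#' @return D_RMS in nm (non-negative scalar).
#' @export
drms <- function(conf, native_set) {
  stopifnot(inherits(conf, "conformation"),
            inherits(native_set, "native_contact_set"))
  key <- atom_key(conf$chain, conf$resid, conf$name)
  ia <- match(atom_key(native_set$chain_a, native_set$resid_a,
                       native_set$name_a), key)
  ib <- match(atom_key(native_set$chain_b, native_set$resid_b,
                       native_set$name_b), key)
  bad <- which(is.na(ia) | is.na(ib))
  if (length(bad))
    stop("atom(s) missing from conformation for native pair(s): ",
         paste(sprintf("%s%d:%s-%s%d:%s", native_set$chain_a[bad],
                       native_set$resid_a[bad], native_set$name_a[bad],
                       native_set$chain_b[bad], native_set$resid_b[bad],
                       native_set$name_b[bad])[seq_len(min(3, length(bad)))],
               collapse = ", "))
  r <- sqrt((conf$x[ia] - conf$x[ib])^2 + (conf$y[ia] - conf$y[ib])^2 +
            (conf$z[ia] - conf$z[ib])^2)
  sqrt(mean((r - native_set$r0)^2))
}

#' Helix-helix crossing angle (pseudo-dihedral)
#'
#' Signed dihedral angle, in the standard right-handed (IUPAC) convention,
#' between the four anchor atoms taken in the order (A_lo, A_hi, B_hi,
#' B_lo) - for glycophorin, the C-alpha atoms of residues A78, A88, B88,
#' B78. Returned in (-pi, pi]; a right-handed native crossing gives a
#' negative angle. Planar cis arrangements give 0, trans gives pi.
#'
#' @param conf a [conformation()].
#' @param anchors data.frame with columns `chain`, `resid` and optionally
#'   `name` (default `"CA"`), one row per anchor, in dihedral order.
#' @return crossing angle in radians.
#' @export
crossing_angle <- function(conf, anchors) {
  stopifnot(inherits(conf, "conformation"), nrow(anchors) == 4L)
  if (is.null(anchors$name)) anchors$name <- "CA"
  key <- atom_key(conf$chain, conf$resid, conf$name)
  idx <- match(atom_key(anchors$chain, anchors$resid, anchors$name), key)
  if (anyNA(idx))
    stop("anchor atom(s) not found: ",
         paste(sprintf("%s%d:%s", anchors$chain, anchors$resid,
                       anchors$name)[is.na(idx)], collapse = ", "))
  p <- as.matrix(conf[idx, c("x", "y", "z")])
  dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
}

#' Signed dihedral of four points (IUPAC convention)
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in (-pi, pi].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("collinear anchor atoms: dihedral undefined")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Parameters of the hybrid coordinate X
#'
#' `X = D_RMS/nm + mu * theta/rad`: a dimensionless linear combination of
#' the distance RMSD and the crossing angle. The mixing coefficient `mu`
#' is chosen to maximize the free-energy barrier between bound and unbound
#' states (see [scan_mu()]); 0.1 is near-optimal for the glycophorin
#' system and is the default.
#'
#' @param mu non-negative mixing coefficient.
#' @return object of class `hybrid_cv_params`.
#' @export
hybrid_cv_params <- function(mu = 0.1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0)
  structure(list(mu = mu, drms_unit = "nm", theta_unit = "rad"),
            class = "hybrid_cv_params")
}

#' Hybrid collective variable X
#'
#' @param d_rms distance RMSD in nm (numeric, vectorized).
#' @param theta crossing angle in rad.
#' @param params a [hybrid_cv_params()] (or a bare `mu` value).
#' @return dimensionless X = d_rms + mu * theta.
#' @export
hybrid_cv <- function(d_rms, theta, params = hybrid_cv_params()) {
  if (is.numeric(params)) params <- hybrid_cv_params(params)
  stopifnot(all(is.finite(d_rms)), all(is.finite(theta)))
  d_rms + params$mu * theta
}

#' Inter-chain residue contact map
#'
#' A residue pair (one residue from each chain) is in contact when any pair
#' of heavy atoms, one from each residue, is within `cutoff` (strict `<`).
#' The map covers all residues of both chains; the native-set residue-range
#' restriction does not apply here.
#'
#' @param conf a [conformation()].
#' @param cutoff contact cutoff in nm (default 0.45).
#' @return a `contact_map`: logical matrix (rows = chain-A residues,
#'   columns = chain-B residues, dimnames = residue indices) with
#'   attribute `cutoff`.
#' @export
contact_map <- function(conf, cutoff = 0.45) {
  stopifnot(inherits(conf, "conformation"))
  ch <- sort(unique(conf$chain))
  a <- conf[conf$chain == ch[1] & conf$heavy, , drop = FALSE]
  b <- conf[conf$chain == ch[2] & conf$heavy, , drop = FALSE]
  ra <- sort(unique(a$resid)); rb <- sort(unique(b$resid))
  d <- pair_distances(a, b)
  m <- matrix(FALSE, length(ra), length(rb), dimnames = list(ra, rb))
  ia <- match(a$resid, ra); ib <- match(b$resid, rb)
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(hit)) m[cbind(ia[hit[, 1]], ib[hit[, 2]])] <- TRUE
  attr(m, "cutoff") <- cutoff
  class(m) <- c("contact_map", class(m))
  m
}

#' CV time series of a conformation ensemble
#'
#' Convenience wrapper computing D_RMS, theta and X for a list of
#' conformations, returned as a tidy table.
#'
#' @param confs list of [conformation()] objects.
#' @param native_set a [build_native_set()] result.
#' @param anchors anchor table for [crossing_angle()].
#' @param params a [hybrid_cv_params()].
#' @param dt frame interval for the `time` column.
#' @return data.frame with `frame`, `time`, `drms`, `theta`, `x`.
#' @export
cv_series <- function(confs, native_set, anchors,
                      params = hybrid_cv_params(), dt = 1) {
  dr <- vapply(confs, drms, numeric(1), native_set = native_set)
  th <- vapply(confs, crossing_angle, numeric(1), anchors = anchors)
  data.frame(frame = seq_along(confs) - 1L, time = (seq_along(confs) - 1L) * dt,
             drms = dr, theta = th, x = hybrid_cv(dr, th, params))
}

#' Write a CV time series as a tab-separated table
#'
#' @param series data.frame as returned by [cv_series()].
#' @param path output file.
#' @export
write_cv_table <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
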