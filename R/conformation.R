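#' Labelled two-chain conformations
#'
#' The unit every collective variable and contact map is computed from: a
#' table of atoms with chain label, residue index, atom name, heavy-atom
#' flag, and 3D coordinates in nanometres. Exactly two chains are required.
#'
#' @param chain character vector of chain labels (exactly two distinct).
#' @param resid integer residue indices, non-decreasing within each chain.
#' @param name atom names (e.g. `"CA"`).
#' @param x,y,z coordinates in nm; must be finite.
#' @param heavy logical heavy-atom flags (default all `TRUE`).
#' @return a `conformation`, a data.frame with the columns above.
#' @export
conformation <- function(chain, resid, name, x, y, z, heavy = TRUE) {
  df <- data.frame(chain = as.character(chain), resid = as.integer(resid),
                   name = as.character(name), heavy = rep_len(heavy,
                   length(chain)), x = as.numeric(x), y = as.numeric(y),
                   z = as.numeric(z), stringsAsFactors = FALSE)
  validate_conformation(df)
  class(df) <- c("conformation", "data.frame")
  df
}

validate_conformation <- function(df) {
  ch <- unique(df$chain)
  if (length(ch) != 2L)
    stop("a conformation must contain exactly two chains (found ",
         length(ch), ")")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z)))
    stop("coordinates must be finite")
  for (c in ch) {
    r <- df$resid[df$chain == c]
    if (any(diff(r) < 0))
      stop("residue indexing must be non-decreasing within chain ", c)
  }
  invisible(df)
}

#' @export
print.conformation <- function(x, ...) {
  ch <- table(x$chain)
  cat("<conformation>", nrow(x), "atoms; chains:",
      paste(sprintf("%s (%d)", names(ch), ch), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a rigid-body transform to a conformation
#'
#' @param conf a [conformation()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector.
#' @return the transformed conformation.
#' @export
transform_conformation <- function(conf, rotation = diag(3),
                                   translation = c(0, 0, 0)) {
  xyz <- as.matrix(conf[, c("x", "y", "z")]) %*% t(rotation)
  conf$x <- xyz[, 1] + translation[1]
  conf$y <- xyz[, 2] + translation[2]
  conf$z <- xyz[, 3] + translation[3]
  conf
}

#' Minimal PDB text I/O for two-chain conformations
#'
#' Writes/reads the coordinate records of a conformation in PDB format
#' (coordinates converted between nm and the PDB's Angstrom). Only ATOM
#' records are handled; this is a light-weight exchange format for the
#' synthetic systems, not a general-purpose PDB parser.
#'
#' @param conf a [conformation()].
#' @param path file path.
#' @export
write_conformation_pdb <- function(conf, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(conf)), substr(conf$name, 1, 4), "GLY", conf$chain,
    conf$resid, conf$x * 10, conf$y * 10, conf$z * 10)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_conformation_pdb
#' @export
read_conformation_pdb <- function(path) {
  ln <- readLines(path)
  ln <- ln[startsWith(ln, "ATOM  ") | startsWith(ln, "HETATM")]
  if (!length(ln)) stop("no ATOM records in ", path)
  nm <- trimws(substr(ln, 13, 16))
  conformation(chain = trimws(substr(ln, 22, 22)),
               resid = as.integer(substr(ln, 23, 26)),
               name = nm,
               x = as.numeric(substr(ln, 31, 38)) / 10,
               y = as.numeric(substr(ln, 39, 46)) / 10,
               z = as.numeric(substr(ln, 47, 54)) / 10,
               heavy = !startsWith(nm, "H"))
}
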