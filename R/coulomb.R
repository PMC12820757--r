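#' Coulomb matrix of a molecule
#'
#' The classic symmetric N x N representation with `0.5 * Z_i^2.4` on the
#' diagonal and `Z_i * Z_j / r_ij` off the diagonal, interatomic distances in
#' Bohr (the original convention for this descriptor; input coordinates are
#' Angstrom and converted internally).
#'
#' @param mol a [molecule()].
#' @return symmetric numeric matrix, one row/column per atom.
#' @export
#' @examples
#' h <- molecule("H", c(0, 0, 0))
#' coulomb_matrix(h)  # [[0.5]]
coulomb_matrix <- function(mol) {
  stopifnot(inherits(mol, "qd_molecule"))
  z <- mol$Z
  n <- length(z)
  cm <- diag(0.5 * z^2.4, n, n)
  if (n > 1L) {
    r_bohr <- .pair_dist(mol$coords) / .BOHR_A
    off <- upper.tri(r_bohr)
    if (any(r_bohr[off] <= 0))
      stop("degenerate geometry: coincident atoms in ", mol$id, call. = FALSE)
    zz <- outer(z, z)
    cm[off] <- zz[off] / r_bohr[off]
    cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
  }
  cm
}
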