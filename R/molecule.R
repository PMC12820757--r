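#' Construct a molecule
#'
#' A molecule is a light S3 record: ordered element symbols, atomic numbers,
#' and an N x 3 matrix of Cartesian coordinates in Angstrom, plus optional
#' metadata (SMILES, conformer id, total tight-binding energy in eV).
#'
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric N x 3 matrix (Angstrom) or anything coercible.
#' @param id molecule identifier; defaults to `"mol"`.
#' @param smiles optional SMILES string (metadata only, never parsed).
#' @param conformer_id optional conformer label.
#' @param energy_tb optional total tight-binding energy in eV.
#' @return object of class `"qd_molecule"`.
#' @export
#' @examples
#' m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)), id = "h2")
#' n_atoms(m)
molecule <- function(elements, coords, id = "mol", smiles = NULL,
                     conformer_id = NULL, energy_tb = NULL) {
  elements <- as.character(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) < 1L)
    stop("a molecule needs at least one atom", call. = FALSE)
  if (nrow(coords) != length(elements))
    stop("coords must have one row per atom", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  z <- atomic_number(elements)
  structure(
    list(id = as.character(id), elements = elements, Z = z, coords = coords,
         smiles = smiles, conformer_id = conformer_id,
         energy_tb = if (is.null(energy_tb)) NULL else as.numeric(energy_tb)),
    class = "qd_molecule")
}

#' @export
print.qd_molecule <- function(x, ...) {
  comp <- table(x$elements)
  formula <- paste0(names(comp), ifelse(comp > 1L, comp, ""), collapse = "")
  cat("<molecule ", x$id, "> ", formula, ", ", length(x$elements),
      " atoms", sep = "")
  if (!is.null(x$energy_tb)) cat(sprintf(", E_tb = %.6f eV", x$energy_tb))
  cat("\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `qd_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "qd_molecule"))
  length(mol$elements)
}

# all pairwise Euclidean distances, Angstrom
.pair_dist <- function(coords) as.matrix(stats::dist(coords))
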