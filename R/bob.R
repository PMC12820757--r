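#' Fit a Bag-of-Bonds bag layout on a dataset
#'
#' Scans every molecule and sizes one "atom bag" per element (max atom count
#' over the dataset) and one "bond bag" per unordered element pair (max pair
#' count), so that every molecule's bagged Coulomb-matrix entries fit with
#' zero padding and all vectors share one length. Bags are ordered
#' canonically: atom bags by ascending atomic number, then bond bags by
#' ascending (Z, Z') pairs.
#'
#' @param molecules list of [molecule()]s (or a [qd_dataset()]).
#' @return object of class `"qd_bagspec"` with `universe` (atomic numbers),
#'   `atom_bags` and `bond_bags` (named integer sizes) and `length`.
#' @export
fit_bag_spec <- function(molecules) {
  if (inherits(molecules, "qd_dataset")) molecules <- molecules$molecules
  if (!length(molecules)) stop("empty dataset", call. = FALSE)
  universe <- sort(unique(unlist(lapply(molecules, function(m) m$Z))))
  atom_bags <- stats::setNames(integer(length(universe)),
                               element_symbol(universe))
  pairs <- .pair_labels(universe)
  bond_bags <- stats::setNames(integer(nrow(pairs)), pairs$label)
  for (m in molecules) {
    counts <- table(factor(m$Z, levels = universe))
    atom_bags <- pmax(atom_bags, as.integer(counts))
    cnt <- as.integer(counts)
    same <- (cnt * (cnt - 1L)) %/% 2L
    for (k in seq_len(nrow(pairs))) {
      i <- match(pairs$z1[k], universe); j <- match(pairs$z2[k], universe)
      bond_bags[k] <- max(bond_bags[k],
                          if (i == j) same[i] else cnt[i] * cnt[j])
    }
  }
  structure(list(universe = universe, atom_bags = atom_bags,
                 bond_bags = bond_bags,
                 length = sum(atom_bags) + sum(bond_bags)),
            class = "qd_bagspec")
}

# unordered element pairs of a universe, canonical (Z <= Z') order
.pair_labels <- function(universe) {
  idx <- which(upper.tri(diag(length(universe)), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  z1 <- universe[idx[, 1]]; z2 <- universe[idx[, 2]]
  data.frame(z1 = z1, z2 = z2,
             label = paste0(element_symbol(z1), element_symbol(z2)),
             stringsAsFactors = FALSE)
}

#' @export
print.qd_bagspec <- function(x, ...) {
  cat("<bag spec> universe {", paste(element_symbol(x$universe),
                                     collapse = ", "),
      "}, vector length ", x$length, "\n", sep = "")
  invisible(x)
}

#' Bag-of-Bonds vector of one molecule
#'
#' Bags the molecule's Coulomb-matrix entries: each atom bag holds that
#' element's diagonal entries sorted descending and zero-padded; each bond bag
#' holds the pair type's off-diagonal entries sorted descending and
#' zero-padded; bags are concatenated in the spec's canonical order. The
#' result is invariant to atom permutation and rigid motion.
#'
#' @param mol a [molecule()].
#' @param spec a [fit_bag_spec()] covering the molecule's elements and counts.
#' @return named numeric vector of length `spec$length`.
#' @export
bob_vector <- function(mol, spec) {
  stopifnot(inherits(mol, "qd_molecule"), inherits(spec, "qd_bagspec"))
  if (!all(mol$Z %in% spec$universe))
    stop("spec mismatch: molecule ", mol$id,
         " contains elements outside the bag universe", call. = FALSE)
  cm <- coulomb_matrix(mol)
  z <- mol$Z
  out <- numeric(0)
  labels <- character(0)
  for (k in seq_along(spec$universe)) {
    zk <- spec$universe[k]
    vals <- sort(diag(cm)[z == zk], decreasing = TRUE)
    size <- spec$atom_bags[k]
    if (length(vals) > size)
      stop("spec mismatch: atom bag ", names(spec$atom_bags)[k],
           " overflows", call. = FALSE)
    out <- c(out, c(vals, numeric(size - length(vals))))
    labels <- c(labels, paste0(names(spec$atom_bags)[k], "_",
                               seq_len(size)))
  }
  pairs <- .pair_labels(spec$universe)
  for (k in seq_len(nrow(pairs))) {
    ii <- which(z == pairs$z1[k]); jj <- which(z == pairs$z2[k])
    if (pairs$z1[k] == pairs$z2[k]) {
      sel <- if (length(ii) > 1L) t(utils::combn(ii, 2L)) else
        matrix(integer(0), 0, 2)
    } else {
      sel <- as.matrix(expand.grid(ii, jj))
    }
    vals <- sort(cm[sel], decreasing = TRUE)
    size <- spec$bond_bags[k]
    if (length(vals) > size)
      stop("spec mismatch: bond bag ", pairs$label[k], " overflows",
           call. = FALSE)
    out <- c(out, c(vals, numeric(size - length(vals))))
    labels <- c(labels, paste0(pairs$label[k], "_", seq_len(size)))
  }
  stats::setNames(out, labels)
}
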