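#' Minimal RMSD between two conformers (Kabsch superposition)
#'
#' Removes the centroids, finds the optimal proper rotation by singular value
#' decomposition of the covariance matrix (with the determinant sign fix that
#' excludes reflections), and returns the root-mean-square deviation of the
#' superposed coordinates. Atom correspondence is positional: both molecules
#' must list the same elements in the same order (no matching search).
#'
#' @param a,b [molecule()]s with identical element sequences.
#' @param hydrogens include hydrogen atoms (default `TRUE`).
#' @return RMSD in Angstrom; 0 iff the structures are congruent under proper
#'   rotation plus translation.
#' @export
kabsch_rmsd <- function(a, b, hydrogens = TRUE) {
  stopifnot(inherits(a, "qd_molecule"), inherits(b, "qd_molecule"))
  if (!identical(a$elements, b$elements))
    stop("element sequences differ; atoms must correspond positionally",
         call. = FALSE)
  keep <- if (hydrogens) seq_along(a$elements) else which(a$elements != "H")
  if (!length(keep)) stop("no atoms left after removing hydrogens",
                          call. = FALSE)
  p <- a$coords[keep, , drop = FALSE]
  q <- b$coords[keep, , drop = FALSE]
  p <- sweep(p, 2, colMeans(p))
  q <- sweep(q, 2, colMeans(q))
  s <- svd(crossprod(q, p))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(max(0, mean(rowSums((q %*% rot - p)^2))))
}

#' Bundle conformers of one molecule
#'
#' @param id molecule identifier shared by the conformers.
#' @param conformers list of [molecule()]s with identical element multisets.
#' @param energies per-conformer total energies in eV; taken from each
#'   molecule's `energy_tb` when omitted.
#' @return object of class `"qd_ensemble"`.
#' @export
conformer_ensemble <- function(id, conformers, energies = NULL) {
  stopifnot(is.list(conformers), length(conformers) >= 1L)
  comp <- lapply(conformers, function(m) sort(m$Z))
  if (!all(vapply(comp, identical, logical(1), comp[[1]])))
    stop("conformers must share one element composition", call. = FALSE)
  if (is.null(energies)) {
    energies <- vapply(conformers, function(m)
      if (is.null(m$energy_tb)) NA_real_ else m$energy_tb, numeric(1))
  }
  energies <- as.numeric(energies)
  if (length(energies) != length(conformers) || anyNA(energies) ||
      !all(is.finite(energies)))
    stop("finite energies required, one per conformer", call. = FALSE)
  structure(list(id = as.character(id), conformers = conformers,
                 energies = energies),
            class = "qd_ensemble")
}

#' @export
print.qd_ensemble <- function(x, ...) {
  cat("<conformer ensemble ", x$id, "> ", length(x$conformers),
      " conformers, E range [",
      sprintf("%.4f, %.4f", min(x$energies), max(x$energies)), "] eV\n",
      sep = "")
  invisible(x)
}

#' Curation thresholds
#'
#' @param energy_window admission window above the reference energy, in
#'   kcal/mol (default 12.0; converted to eV internally).
#' @param rmsd_keep minimum RMSD to the reference for a conformer to count as
#'   distinct, in Angstrom (default 0.1).
#' @param cluster_cut cut height for RMSD hierarchical clustering, Angstrom
#'   (default 1.0).
#' @param allowed_elements element symbols admitted by [filter_elements()];
#'   default drug-like set without Si.
#' @param hydrogens include hydrogens in RMSD computations.
#' @return object of class `"qd_curation_config"`.
#' @export
curation_config <- function(energy_window = 12.0, rmsd_keep = 0.1,
                            cluster_cut = 1.0,
                            allowed_elements = c("H", "C", "N", "O", "F",
                                                 "P", "S", "Cl", "Br", "I"),
                            hydrogens = TRUE) {
  stopifnot(energy_window > 0, rmsd_keep > 0, cluster_cut >= 0)
  structure(list(energy_window = energy_window, rmsd_keep = rmsd_keep,
                 cluster_cut = cluster_cut,
                 allowed_elements = allowed_elements,
                 hydrogens = isTRUE(hydrogens)),
            class = "qd_curation_config")
}

#' Admit conformers by energy window and RMSD distinctness
#'
#' Keeps the reference conformer, plus every conformer whose energy lies
#' within `energy_window` kcal/mol above the reference energy AND whose RMSD
#' to the reference is at least `rmsd_keep` Angstrom (duplicates of the
#' reference are redundant and dropped).
#'
#' @param ens a [conformer_ensemble()].
#' @param ref index of the reference conformer.
#' @param config a [curation_config()].
#' @return the admitted ensemble, with a `report` attribute listing counts
#'   kept/discarded and the reason per conformer.
#' @export
admit_ensemble <- function(ens, ref = 1L, config = curation_config()) {
  stopifnot(inherits(ens, "qd_ensemble"),
            inherits(config, "qd_curation_config"))
  nc <- length(ens$conformers)
  if (ref < 1L || ref > nc) stop("ref index out of range", call. = FALSE)
  window_ev <- config$energy_window * .KCALMOL_EV
  e_ref <- ens$energies[ref]
  reason <- character(nc)
  for (i in seq_len(nc)) {
    if (i == ref) { reason[i] <- "reference"; next }
    if (ens$energies[i] > e_ref + window_ev) {
      reason[i] <- "energy_window"
    } else {
      r <- kabsch_rmsd(ens$conformers[[ref]], ens$conformers[[i]],
                       hydrogens = config$hydrogens)
      reason[i] <- if (r < config$rmsd_keep) "rmsd_duplicate" else "kept"
    }
  }
  keep <- reason %in% c("reference", "kept")
  out <- conformer_ensemble(ens$id, ens$conformers[keep],
                            ens$energies[keep])
  attr(out, "report") <- data.frame(
    conformer = seq_len(nc), energy = ens$energies, status = reason,
    stringsAsFactors = FALSE)
  out
}

#' Representative conformers by RMSD hierarchical clustering
#'
#' Builds the pairwise Kabsch RMSD matrix, clusters it with average-linkage
#' agglomeration, cuts the tree at `cluster_cut` Angstrom, and keeps the
#' lowest-energy member of each cluster. A cut height of 0 keeps every
#' conformer; a cut above the largest pairwise RMSD keeps one.
#'
#' @param ens a [conformer_ensemble()].
#' @param config a [curation_config()].
#' @return a [conformer_ensemble()] of representatives (original order), with
#'   a `clusters` attribute giving each input conformer's cluster id.
#' @export
cluster_conformers <- function(ens, config = curation_config()) {
  stopifnot(inherits(ens, "qd_ensemble"),
            inherits(config, "qd_curation_config"))
  nc <- length(ens$conformers)
  if (nc == 1L) {
    out <- ens
    attr(out, "clusters") <- 1L
    return(out)
  }
  d <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc)
    d[i, j] <- d[j, i] <- kabsch_rmsd(ens$conformers[[i]],
                                      ens$conformers[[j]],
                                      hydrogens = config$hydrogens)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = config$cluster_cut)
  reps <- vapply(split(seq_len(nc), cl), function(idx)
    idx[which.min(ens$energies[idx])], integer(1))
  reps <- sort(unname(reps))
  out <- conformer_ensemble(ens$id, ens$conformers[reps], ens$energies[reps])
  attr(out, "clusters") <- cl
  out
}

#' Drop molecules containing disallowed elements
#'
#' Mirrors the dataset-screening step that removes species outside the
#' supported element set (e.g. silicon-containing compounds, absent from the
#' tight-binding parameterization).
#'
#' @param dataset a [qd_dataset()] or list of molecules.
#' @param allowed character vector of allowed element symbols.
#' @return list with `dataset` (filtered, same type as the input) and
#'   `report` (data frame of discarded ids and their offending elements).
#'   Idempotent.
#' @export
filter_elements <- function(dataset,
                            allowed = curation_config()$allowed_elements) {
  is_ds <- inherits(dataset, "qd_dataset")
  mols <- if (is_ds) dataset$molecules else dataset
  bad <- lapply(mols, function(m) setdiff(unique(m$elements), allowed))
  keep <- lengths(bad) == 0L
  report <- data.frame(
    molecule_id = vapply(mols[!keep], function(m) m$id, character(1)),
    offending = vapply(bad[!keep], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  if (is_ds) {
    kept_ids <- vapply(mols[keep], function(m) m$id, character(1))
    tgt <- dataset$targets
    if (!is.null(tgt)) {
      units <- attr(tgt, "units")
      tgt <- tgt[tgt$molecule_id %in% kept_ids, , drop = FALSE]
      tgt <- property_table(as.data.frame(unclass(tgt)), units)
    }
    out <- qd_dataset(mols[keep],
                      dataset$records[intersect(names(dataset$records),
                                                kept_ids)],
                      tgt, dataset$provenance)
  } else out <- mols[keep]
  list(dataset = out, report = report)
}

#' Lowest-energy conformer per molecule
#'
#' @param groups named list of [conformer_ensemble()]s, one per molecule id.
#' @return named list of [molecule()]s: the argmin-energy conformer of each
#'   ensemble (first occurrence wins ties).
#' @export
select_lowest_energy <- function(groups) {
  stopifnot(is.list(groups))
  lapply(groups, function(ens) {
    stopifnot(inherits(ens, "qd_ensemble"))
    ens$conformers[[which.min(ens$energies)]]
  })
}
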