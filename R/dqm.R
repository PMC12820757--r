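#' Electronic descriptor layout
#'
#' Chooses which subsets of the electronic descriptor are emitted and how they
#' are sized. The three subsets, in fixed order:
#' \describe{
#'   \item{glob}{10 global values: `E_Fermi`, `E_band`, `NE`, `E_H0`, `E_scc`,
#'     `E_3rd`, `E_rep`, `E_mbd`, `||mu_TB||`, `E_gap_TB`.}
#'   \item{eMO}{frontier orbital energies: the `n_occ` highest occupied plus
#'     `n_virt` lowest unoccupied eigenvalues in ascending order (default
#'     4 + 4 = 8, a symmetric window around the gap).}
#'   \item{atom}{per-atom Mulliken charges in record order, zero-padded to
#'     `n_max`, the largest atom count in the dataset.}
#' }
#'
#' @param subsets character subset of `c("glob", "eMO", "atom")`.
#' @param n_max padding length for the Mulliken block (must cover the largest
#'   molecule); required when `"atom"` is included.
#' @param n_occ,n_virt frontier window sizes.
#' @param canonical_atom_order if `TRUE`, Mulliken charges are re-ordered by
#'   (Z descending, charge descending) before padding, restoring permutation
#'   invariance that raw atom order lacks. Default `FALSE` (raw record order,
#'   as zero-padding implies).
#' @return object of class `"qd_dqmspec"`.
#' @export
dqm_spec <- function(subsets = c("glob", "eMO", "atom"), n_max = NULL,
                     n_occ = 4L, n_virt = 4L, canonical_atom_order = FALSE) {
  subsets <- match.arg(subsets, c("glob", "eMO", "atom"), several.ok = TRUE)
  if ("atom" %in% subsets && (is.null(n_max) || n_max < 1L))
    stop("the atom subset needs n_max >= 1", call. = FALSE)
  stopifnot(n_occ >= 1L, n_virt >= 1L)
  structure(list(subsets = subsets, n_max = if (is.null(n_max)) NULL
                 else as.integer(n_max),
                 n_occ = as.integer(n_occ), n_virt = as.integer(n_virt),
                 canonical_atom_order = isTRUE(canonical_atom_order)),
            class = "qd_dqmspec")
}

.GLOB_LABELS <- c("E_Fermi", "E_band", "NE", "E_H0", "E_scc", "E_3rd",
                  "E_rep", "E_mbd", "mu_TB_norm", "E_gap_TB")

#' Assemble the electronic descriptor row for one record
#'
#' Concatenates the requested subsets in the fixed order glob, eMO, atom.
#' The frontier window takes the `n_occ` highest occupied and `n_virt` lowest
#' unoccupied eigenvalues, kept ascending so that the gap sits between the
#' `n_occ`-th and `(n_occ+1)`-th entries.
#'
#' @param record a [qm_record()].
#' @param spec a [dqm_spec()]; atom count must not exceed `spec$n_max` and the
#'   record must have enough occupied/virtual orbitals for the window.
#' @param z optional atomic numbers (same order as the Mulliken charges),
#'   needed only for `canonical_atom_order`.
#' @return named numeric vector.
#' @export
#' @examples
#' r <- qm_record(-4, -12, 4, -10, -0.5, -0.05, 0.4, -0.2, c(0.1, 0, 0),
#'                mo_energies = seq(-12, 2, by = 1), homo_index = 8,
#'                mulliken = c(0.05, -0.05))
#' length(build_dqm(r, dqm_spec("eMO")))  # frontier window of 8
build_dqm <- function(record, spec, z = NULL) {
  stopifnot(inherits(record, "qd_qmrecord"), inherits(spec, "qd_dqmspec"))
  out <- numeric(0)
  labels <- character(0)
  if ("glob" %in% spec$subsets) {
    out <- c(out, record$E_Fermi, record$E_band, record$NE, record$E_H0,
             record$E_scc, record$E_3rd, record$E_rep, record$E_mbd,
             record$mu_TB_norm, record$E_gap_TB)
    labels <- c(labels, .GLOB_LABELS)
  }
  if ("eMO" %in% spec$subsets) {
    h <- record$homo_index
    n_orb <- length(record$mo_energies)
    if (h < spec$n_occ || n_orb - h < spec$n_virt)
      stop(sprintf(
        "window error: need %d occupied and %d virtual orbitals, have %d/%d",
        spec$n_occ, spec$n_virt, h, n_orb - h), call. = FALSE)
    idx <- (h - spec$n_occ + 1L):(h + spec$n_virt)
    out <- c(out, record$mo_energies[idx])
    labels <- c(labels, paste0("eps_", seq_along(idx)))
  }
  if ("atom" %in% spec$subsets) {
    q <- record$mulliken
    if (length(q) > spec$n_max)
      stop("padding error: molecule has ", length(q),
           " atoms but n_max is ", spec$n_max, call. = FALSE)
    if (spec$canonical_atom_order) {
      if (is.null(z) || length(z) != length(q))
        stop("canonical atom order needs atomic numbers z", call. = FALSE)
      q <- q[order(-z, -q)]
    }
    out <- c(out, q, numeric(spec$n_max - length(q)))
    labels <- c(labels, paste0("Q_", seq_len(spec$n_max)))
  }
  if (!length(out)) stop("no subsets requested", call. = FALSE)
  stats::setNames(out, labels)
}

#' Electronic descriptor block over a dataset
#'
#' @param records named list of [qm_record()]s (or a [qd_dataset()], in which
#'   case rows follow molecule order and `n_max` defaults to the dataset
#'   maximum).
#' @param spec a [dqm_spec()]; when `NULL` and a dataset is given, the default
#'   full layout is sized from the dataset.
#' @return a [descriptor_block()] named `"DQM"`.
#' @export
dqm_block <- function(records, spec = NULL) {
  zs <- NULL
  if (inherits(records, "qd_dataset")) {
    ds <- records
    ids <- vapply(ds$molecules, function(m) m$id, character(1))
    records <- ds$records[ids]
    zs <- lapply(ds$molecules, function(m) m$Z)
    if (is.null(spec)) spec <- dqm_spec(n_max = dataset_n_max(ds))
  }
  stopifnot(inherits(spec, "qd_dqmspec"))
  rows <- lapply(seq_along(records), function(i)
    build_dqm(records[[i]], spec, z = if (is.null(zs)) NULL else zs[[i]]))
  m <- do.call(rbind, rows)
  descriptor_block("DQM", m, row_ids = names(records))
}
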