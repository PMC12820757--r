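#' Build a property table of regression targets
#'
#' A thin wrapper around a data frame keyed by `(molecule_id, conformer_id)`
#' with one column per target property and a unit label attached to every
#' target column (e.g. `E_AT` in eV, `mu` in e*Angstrom, `alpha` in Bohr^3,
#' `LD50` in log(mol/kg), `logD` dimensionless).
#'
#' @param df data frame with a `molecule_id` column (a `conformer_id` column
#'   is added as `""` when missing) plus numeric target columns.
#' @param units named character vector giving a unit for every target column.
#' @return data frame of class `"qd_property_table"` with a `units` attribute.
#' @export
property_table <- function(df, units) {
  df <- as.data.frame(df)
  if (!"molecule_id" %in% names(df))
    stop("property table needs a molecule_id column", call. = FALSE)
  if (!"conformer_id" %in% names(df)) df$conformer_id <- ""
  targets <- setdiff(names(df), c("molecule_id", "conformer_id"))
  missing_units <- setdiff(targets, names(units))
  if (length(missing_units))
    stop("unit label missing for column(s): ",
         paste(missing_units, collapse = ", "), call. = FALSE)
  key <- paste(df$molecule_id, df$conformer_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (molecule_id, conformer_id) keys", call. = FALSE)
  attr(df, "units") <- units[targets]
  class(df) <- c("qd_property_table", "data.frame")
  df
}

#' Assemble a dataset of molecules, records and targets
#'
#' @param molecules list of [molecule()] objects.
#' @param records named list of [qm_record()]s; names must be molecule ids.
#' @param targets optional [property_table()]; molecule ids must exist.
#' @param provenance free-text metadata string.
#' @return object of class `"qd_dataset"`.
#' @export
qd_dataset <- function(molecules, records = list(), targets = NULL,
                       provenance = "") {
  stopifnot(is.list(molecules))
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule ids", call. = FALSE)
  if (length(records)) {
    if (is.null(names(records)) || !all(names(records) %in% ids))
      stop("every record key must match a molecule id", call. = FALSE)
  }
  if (!is.null(targets) && !all(targets$molecule_id %in% ids))
    stop("every target key must match a molecule id", call. = FALSE)
  structure(list(molecules = molecules, records = records, targets = targets,
                 provenance = provenance),
            class = "qd_dataset")
}

#' @export
print.qd_dataset <- function(x, ...) {
  cat("<dataset> ", length(x$molecules), " molecules, ",
      length(x$records), " tight-binding records, ",
      if (is.null(x$targets)) 0L else nrow(x$targets), " target rows\n",
      sep = "")
  invisible(x)
}

#' Largest atom count in a dataset
#' @param dataset a [qd_dataset()].
#' @return integer, the padding length `n_max`.
#' @export
dataset_n_max <- function(dataset) {
  stopifnot(inherits(dataset, "qd_dataset"))
  if (!length(dataset$molecules)) stop("empty dataset", call. = FALSE)
  max(vapply(dataset$molecules, n_atoms, integer(1)))
}

.mol_to_list <- function(m) {
  list(id = m$id, elements = m$elements,
       coords = unname(m$coords), smiles = m$smiles,
       conformer_id = m$conformer_id, energy_tb = m$energy_tb)
}

.rec_to_list <- function(r) unclass(r)

#' Save a dataset to a single self-describing archive
#'
#' The archive is one hierarchical JSON document (molecules / records /
#' targets / provenance sections plus a format header), written at full float
#' precision so that [load_dataset()] restores every number within 1e-12.
#'
#' @param dataset a [qd_dataset()].
#' @param path file path for the archive.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "qd_dataset"))
  doc <- list(
    format = "quantdesc-dataset", version = 1L,
    provenance = dataset$provenance,
    molecules = lapply(dataset$molecules, .mol_to_list),
    records = lapply(dataset$records, .rec_to_list),
    targets = if (is.null(dataset$targets)) NULL else list(
      units = as.list(attr(dataset$targets, "units")),
      table = as.data.frame(unclass(dataset$targets),
                            stringsAsFactors = FALSE)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' Load a dataset archive
#'
#' Validates the format header and the referential integrity of the archive
#' (every record and target key must resolve to a molecule); a truncated or
#' inconsistent archive raises an error rather than returning partial data.
#'
#' @param path archive path written by [save_dataset()].
#' @return a [qd_dataset()].
#' @export
load_dataset <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = TRUE),
                  error = function(e)
                    stop("cannot load archive: ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(doc$format, "quantdesc-dataset"))
    stop("not a quantdesc dataset archive", call. = FALSE)
  mols <- lapply(doc$molecules, function(m)
    molecule(m$elements, matrix(m$coords, ncol = 3), id = m$id,
             smiles = m$smiles, conformer_id = m$conformer_id,
             energy_tb = m$energy_tb))
  recs <- lapply(doc$records, function(r)
    qm_record(E_Fermi = r$E_Fermi, E_band = r$E_band, NE = r$NE,
              E_H0 = r$E_H0, E_scc = r$E_scc, E_3rd = r$E_3rd,
              E_rep = r$E_rep, E_mbd = r$E_mbd, mu_TB_vec = r$mu_TB_vec,
              mo_energies = r$mo_energies, homo_index = r$homo_index,
              mulliken = r$mulliken, E_gap_TB = r$E_gap_TB,
              charge = r$charge))
  tgt <- NULL
  if (!is.null(doc$targets)) {
    tab <- as.data.frame(doc$targets$table, stringsAsFactors = FALSE)
    tgt <- property_table(tab, unlist(doc$targets$units))
  }
  qd_dataset(mols, recs, tgt, provenance = doc$provenance)
}
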