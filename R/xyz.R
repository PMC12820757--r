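#' Read molecules from XYZ / extended-XYZ text
#'
#' Parses one or more XYZ frames. The second line of each frame (the comment
#' line) may carry `key=value` pairs; `id`, `conformer_id`, `energy` (eV) and
#' `smiles` are recognised and stored on the molecule, anything else is
#' ignored. Frames without an `id` get `"<stem>_<frame>"` synthesised from the
#' file name.
#'
#' @param source path to an XYZ file, or a character vector of lines.
#' @return list of [molecule()] objects, one per frame.
#' @export
#' @examples
#' mols <- read_xyz(c("2", "id=h2 energy=-31.0", "H 0 0 0", "H 0 0 0.74"))
#' mols[[1]]$energy_tb
read_xyz <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    stem <- sub("\\.[^.]*$", "", basename(source))
  } else {
    # split embedded newlines but keep genuinely empty lines
    lines <- unlist(lapply(strsplit(as.character(source), "\n",
                                    fixed = TRUE),
                           function(x) if (length(x)) x else ""))
    stem <- "mol"
  }
  mols <- list()
  i <- 1L
  frame <- 0L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("line ", i, ": malformed atom-count line: ", sQuote(lines[i]),
           call. = FALSE)
    if (i + 1L + n > n_lines)
      stop("line ", i, ": frame declares ", n, " atoms but file ends early",
           call. = FALSE)
    frame <- frame + 1L
    meta <- .parse_xyz_comment(lines[i + 1L])
    elements <- character(n)
    coords <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(tok) < 4L)
        stop("line ", ln, ": expected 'symbol x y z'", call. = FALSE)
      sym <- tok[1]
      if (!(sym %in% .SYMBOLS))
        stop("line ", ln, ": unknown element symbol ", sQuote(sym),
             call. = FALSE)
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop("line ", ln, ": coordinate parse failure", call. = FALSE)
      elements[k] <- sym
      coords[k, ] <- xyz
    }
    id <- if (!is.null(meta$id)) meta$id else paste0(stem, "_", frame)
    mols[[length(mols) + 1L]] <- molecule(
      elements, coords, id = id, smiles = meta$smiles,
      conformer_id = meta$conformer_id, energy_tb = meta$energy)
    i <- i + 2L + n
  }
  mols
}

.parse_xyz_comment <- function(line) {
  out <- list()
  if (is.na(line) || !nzchar(trimws(line))) return(out)
  for (tok in strsplit(trimws(line), "[[:space:]]+")[[1]]) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) out[[kv[1]]] <- kv[2]
  }
  if (!is.null(out$energy)) out$energy <- as.numeric(out$energy)
  out
}

#' Write molecules as (extended-)XYZ text
#'
#' Inverse of [read_xyz()]: metadata goes to `key=value` pairs on the comment
#' line so that read(write(m)) reproduces `m` up to float formatting.
#'
#' @param mols a `qd_molecule` or list of them.
#' @param path optional file path; if `NULL` the lines are returned invisibly.
#' @param digits coordinate print precision (default 12, enough for 1e-9
#'   round-trips).
#' @return character vector of lines, invisibly.
#' @export
write_xyz <- function(mols, path = NULL, digits = 12) {
  if (inherits(mols, "qd_molecule")) mols <- list(mols)
  fmt <- paste0("%.", digits, "g")
  lines <- unlist(lapply(mols, function(m) {
    meta <- c(paste0("id=", m$id),
              if (!is.null(m$conformer_id)) paste0("conformer_id=", m$conformer_id),
              if (!is.null(m$energy_tb)) paste0("energy=", sprintf(fmt, m$energy_tb)),
              if (!is.null(m$smiles)) paste0("smiles=", m$smiles))
    c(as.character(length(m$elements)),
      paste(meta, collapse = " "),
      vapply(seq_along(m$elements), function(k)
        paste(m$elements[k], sprintf(fmt, m$coords[k, 1]),
              sprintf(fmt, m$coords[k, 2]), sprintf(fmt, m$coords[k, 3])),
        character(1)))
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
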