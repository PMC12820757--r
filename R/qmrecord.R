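#' Construct a tight-binding property record
#'
#' Holds the electronic-structure quantities computed for one conformer by a
#' semi-empirical tight-binding run: global energies, the tight-binding dipole,
#' molecular-orbital eigenvalues with the occupied/virtual split, and per-atom
#' Mulliken charges. All energies are in eV, dipoles in e*Angstrom.
#'
#' Invariants checked at construction: `NE > 0`; `mo_energies` ascending;
#' `E_gap_TB` consistent with `eps_LUMO - eps_HOMO` within 1e-6 eV;
#' `mu_TB_norm` equal to `||mu_TB_vec||` within 1e-9; Mulliken charges of a
#' neutral molecule summing to 0 within 1e-4.
#'
#' @param E_Fermi,E_band,E_H0,E_scc,E_3rd,E_rep,E_mbd global energies (eV):
#'   Fermi level, band energy, reference-density energy, self-consistent-charge
#'   energy, third-order correction, repulsion energy, many-body dispersion
#'   energy.
#' @param NE number of electrons (> 0).
#' @param mu_TB_vec tight-binding dipole vector, length 3, e*Angstrom.
#' @param mo_energies orbital eigenvalues in ascending order (eV).
#' @param homo_index index (1-based) of the highest occupied orbital within
#'   `mo_energies`; if `NULL`, inferred as `NE/2` assuming a closed shell.
#' @param mulliken per-atom net Mulliken charges (e).
#' @param E_gap_TB optional HOMO-LUMO gap (eV); computed from the eigenvalues
#'   when omitted, cross-checked when given.
#' @param charge net molecular charge; the Mulliken sum must match it.
#' @return object of class `"qd_qmrecord"`.
#' @export
qm_record <- function(E_Fermi, E_band, NE, E_H0, E_scc, E_3rd, E_rep, E_mbd,
                      mu_TB_vec, mo_energies, homo_index = NULL, mulliken,
                      E_gap_TB = NULL, charge = 0) {
  NE <- as.numeric(NE)
  if (!is.finite(NE) || NE <= 0) stop("NE must be > 0", call. = FALSE)
  mu_TB_vec <- as.numeric(mu_TB_vec)
  if (length(mu_TB_vec) != 3L) stop("mu_TB_vec must have length 3",
                                    call. = FALSE)
  mo_energies <- as.numeric(mo_energies)
  if (is.unsorted(mo_energies))
    stop("mo_energies must be sorted ascending", call. = FALSE)
  if (is.null(homo_index)) homo_index <- as.integer(round(NE / 2))
  homo_index <- as.integer(homo_index)
  if (homo_index < 1L || homo_index >= length(mo_energies))
    stop("homo_index must leave at least one virtual orbital", call. = FALSE)
  gap <- mo_energies[homo_index + 1L] - mo_energies[homo_index]
  if (!is.null(E_gap_TB) && abs(E_gap_TB - gap) > 1e-6)
    stop(sprintf(
      "integrity error: stated gap %.8f eV differs from eigenvalue gap %.8f eV",
      E_gap_TB, gap), call. = FALSE)
  mulliken <- as.numeric(mulliken)
  if (abs(sum(mulliken) - charge) > 1e-4)
    stop(sprintf("Mulliken charges sum to %.6f, expected net charge %g",
                 sum(mulliken), charge), call. = FALSE)
  glob <- as.numeric(c(E_Fermi, E_band, E_H0, E_scc, E_3rd, E_rep, E_mbd))
  if (!all(is.finite(glob))) stop("energies must be finite", call. = FALSE)
  structure(
    list(E_Fermi = glob[1], E_band = glob[2], NE = NE, E_H0 = glob[3],
         E_scc = glob[4], E_3rd = glob[5], E_rep = glob[6], E_mbd = glob[7],
         mu_TB_vec = mu_TB_vec, mu_TB_norm = sqrt(sum(mu_TB_vec^2)),
         E_gap_TB = gap, mo_energies = mo_energies, homo_index = homo_index,
         mulliken = mulliken, charge = charge),
    class = "qd_qmrecord")
}

#' @export
print.qd_qmrecord <- function(x, ...) {
  cat(sprintf(
    "<tight-binding record> %d atoms, NE = %g, gap = %.4f eV, |mu| = %.4f eA\n",
    length(x$mulliken), x$NE, x$E_gap_TB, x$mu_TB_norm))
  invisible(x)
}

# field synonyms shared by both parser dialects
.TB_ENERGY_KEYS <- c(
  E_Fermi = "fermi", E_band = "band", E_H0 = "h0|reference",
  E_scc = "scc|self.consistent", E_3rd = "3rd|third", E_rep = "rep",
  E_mbd = "mbd|dispersion")

#' Parse tight-binding results text into a property record
#'
#' Two text dialects are supported and documented byte-exactly by the fixture
#' files under `inst/extdata/`:
#' \describe{
#'   \item{`"detailed"`}{free-text blocks in the style of verbose tight-binding
#'     output: labelled energy lines (`"Fermi level: -4.20 eV"`), a
#'     `"Dipole moment: x y z <unit>"` line, an `"Eigenvalues"` block with one
#'     `energy occupation` pair per line, and a `"Mulliken charges"` block.}
#'   \item{`"tagged"`}{`key = values [unit]` lines, one field per key
#'     (`fermi_level`, `band_energy`, `n_electrons`, `e_h0`, `e_scc`, `e_3rd`,
#'     `e_rep`, `e_mbd`, `dipole`, `eigenvalues`, `occupations`, `mulliken`,
#'     optionally `charge`, `gap`).}
#' }
#' Energies tagged `H`/`Ha`/`Hartree` are converted to eV; dipoles tagged
#' `au`/`ea0` (e*Bohr) to e*Angstrom. The occupied/virtual split is taken from
#' occupations where present, otherwise inferred from the electron count.
#'
#' @param source path to a results file, or a character vector of lines.
#' @param dialect `"detailed"` or `"tagged"`.
#' @return a [qm_record()].
#' @export
parse_tb_results <- function(source, dialect = c("detailed", "tagged")) {
  dialect <- match.arg(dialect)
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    lines <- readLines(source, warn = FALSE)
  else
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  f <- if (dialect == "detailed") .parse_tb_detailed(lines)
       else .parse_tb_tagged(lines)
  for (fld in c("E_Fermi", "E_band", "NE", "E_H0", "E_scc", "E_3rd", "E_rep",
                "E_mbd", "dipole", "eigenvalues", "mulliken"))
    if (is.null(f[[fld]]))
      stop("parse error: missing mandatory field ", sQuote(fld), call. = FALSE)
  homo <- if (!is.null(f$occupations)) {
    occ <- which(f$occupations > 0.5)
    if (length(occ) == 0L) stop("no occupied orbitals", call. = FALSE)
    max(occ)
  } else NULL
  ord <- order(f$eigenvalues)
  eig <- f$eigenvalues[ord]
  if (!is.null(homo)) {
    # occupations must already align with ascending order
    if (!identical(ord, seq_along(eig)))
      stop("eigenvalues not ascending; cannot align occupations",
           call. = FALSE)
  }
  qm_record(E_Fermi = f$E_Fermi, E_band = f$E_band, NE = f$NE, E_H0 = f$E_H0,
            E_scc = f$E_scc, E_3rd = f$E_3rd, E_rep = f$E_rep,
            E_mbd = f$E_mbd, mu_TB_vec = f$dipole, mo_energies = eig,
            homo_index = homo, mulliken = f$mulliken, E_gap_TB = f$gap,
            charge = if (is.null(f$charge)) 0 else f$charge)
}

.energy_to_ev <- function(x, unit) {
  if (is.null(unit) || unit %in% c("eV", "ev")) return(x)
  if (tolower(unit) %in% c("h", "ha", "hartree")) return(x * .HARTREE_EV)
  stop("unknown energy unit ", sQuote(unit), call. = FALSE)
}

.dipole_to_ea <- function(x, unit) {
  if (is.null(unit) || tolower(unit) %in% c("ea", "e*a", "eang")) return(x)
  if (tolower(unit) %in% c("au", "ea0", "debye_no")) return(x * .BOHR_A)
  stop("unknown dipole unit ", sQuote(unit), call. = FALSE)
}

.num_tail <- function(line) {
  # numbers after the colon, with optional trailing unit word
  rhs <- sub("^[^:]*:", "", line)
  toks <- strsplit(trimws(rhs), "[[:space:]]+")[[1]]
  unit <- NULL
  if (length(toks) && suppressWarnings(is.na(as.numeric(toks[length(toks)])))) {
    unit <- toks[length(toks)]
    toks <- toks[-length(toks)]
  }
  list(values = as.numeric(toks), unit = unit)
}

.parse_tb_detailed <- function(lines) {
  f <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    low <- tolower(ln)
    if (grepl("fermi", low)) {
      v <- .num_tail(ln); f$E_Fermi <- .energy_to_ev(v$values[1], v$unit)
    } else if (grepl("band", low)) {
      v <- .num_tail(ln); f$E_band <- .energy_to_ev(v$values[1], v$unit)
    } else if (grepl("number of electrons|electrons:", low)) {
      f$NE <- .num_tail(ln)$values[1]
    } else if (grepl("h0|reference density", low)) {
      v <- .num_tail(ln); f$E_H0 <- .energy_to_ev(v$values[1], v$unit)
    } else if (grepl("scc|self.consistent", low)) {
      v <- .num_tail(ln); f$E_scc <- .energy_to_ev(v$values[1], v$unit)
    } else if (grepl("third|3rd", low)) {
      v <- .num_tail(ln); f$E_3rd <- .energy_to_ev(v$values[1], v$unit)
    } else if (grepl("repuls", low)) {
      v <- .num_tail(ln); f$E_rep <- .energy_to_ev(v$values[1], v$unit)
    } else if (grepl("mbd|dispersion", low)) {
      v <- .num_tail(ln); f$E_mbd <- .energy_to_ev(v$values[1], v$unit)
    } else if (grepl("net charge", low)) {
      f$charge <- .num_tail(ln)$values[1]
    } else if (grepl("dipole", low)) {
      v <- .num_tail(ln)
      if (length(v$values) != 3L)
        stop("parse error: dipole line needs 3 components", call. = FALSE)
      f$dipole <- .dipole_to_ea(v$values, v$unit)
    } else if (grepl("^\\s*eigenvalues", low)) {
      unit <- if (grepl("/\\s*h", low)) "H" else "eV"
      eig <- numeric(0); occ <- numeric(0)
      while (i + 1L <= n && grepl("^\\s*-?[0-9]", lines[i + 1L])) {
        i <- i + 1L
        toks <- as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]])
        eig <- c(eig, .energy_to_ev(toks[1], unit))
        occ <- c(occ, if (length(toks) >= 2L) toks[2] else NA_real_)
      }
      f$eigenvalues <- eig
      if (!anyNA(occ)) f$occupations <- occ
    } else if (grepl("mulliken", low)) {
      q <- numeric(0)
      while (i + 1L <= n && grepl("^\\s*-?[0-9.]", lines[i + 1L])) {
        i <- i + 1L
        toks <- as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]])
        q <- c(q, toks[length(toks)])  # last column = net charge
      }
      f$mulliken <- q
    }
    i <- i + 1L
  }
  f
}

.parse_tb_tagged <- function(lines) {
  keymap <- c(fermi_level = "E_Fermi", band_energy = "E_band",
              n_electrons = "NE", e_h0 = "E_H0", e_scc = "E_scc",
              e_3rd = "E_3rd", e_rep = "E_rep", e_mbd = "E_mbd",
              dipole = "dipole", eigenvalues = "eigenvalues",
              occupations = "occupations", mulliken = "mulliken",
              charge = "charge", gap = "gap")
  f <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("line ", i, ": expected 'key = values [unit]'", call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% names(keymap)) next
    v <- .num_tail(paste0(":", kv[2]))
    fld <- keymap[[key]]
    f[[fld]] <- switch(fld,
      dipole = .dipole_to_ea(v$values, v$unit),
      eigenvalues = .energy_to_ev(v$values, v$unit),
      NE = , occupations = , mulliken = , charge = v$values,
      .energy_to_ev(v$values, v$unit))
    if (fld %in% c("E_Fermi", "E_band", "E_H0", "E_scc", "E_3rd", "E_rep",
                   "E_mbd", "NE", "charge", "gap"))
      f[[fld]] <- f[[fld]][1]
  }
  f
}
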