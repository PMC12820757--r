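# Element symbol <-> atomic number lookup (H..Rn covers drug-like chemistry).

.SYMBOLS <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe",
  "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy",
  "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt",
  "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

#' Atomic numbers for element symbols
#'
#' @param symbols character vector of element symbols (case-sensitive, e.g.
#'   `"Cl"` not `"CL"`).
#' @return integer vector of atomic numbers.
#' @export
#' @examples
#' atomic_number(c("H", "C", "Cl"))
atomic_number <- function(symbols) {
  z <- match(symbols, .SYMBOLS)
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.integer(z)
}

#' Element symbols for atomic numbers
#'
#' @param z integer vector of atomic numbers in 1..86.
#' @return character vector of symbols.
#' @export
element_symbol <- function(z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L) || any(z > length(.SYMBOLS)))
    stop("atomic numbers must be integers in 1..", length(.SYMBOLS),
         call. = FALSE)
  .SYMBOLS[z]
}

# Bohr radius in Angstrom; Hartree in eV (CODATA).
.BOHR_A <- 0.529177210903
.HARTREE_EV <- 27.211386245988
.KCALMOL_EV <- 0.04336410424

#' Physical constants used internally
#'
#' Unit conventions are fixed package-wide: coordinates in Angstrom, energies
#' in eV, dipoles in e*Angstrom, polarizabilities in Bohr^3. Parsers convert at
#' read time.
#'
#' @return named list with `bohr_angstrom`, `hartree_ev`, `kcalmol_ev`.
#' @export
qd_constants <- function() {
  list(bohr_angstrom = .BOHR_A, hartree_ev = .HARTREE_EV,
       kcalmol_ev = .KCALMOL_EV)
}
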