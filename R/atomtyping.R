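# Element symbols indexed by atomic number (1..103).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr")

.TYPING_SCHEME_VERSION <- "abbcdd/1.0"

#' Version string of the atom-typing scheme
#'
#' Recorded in every fitted model; a persisted model refuses to score
#' spectra produced by a different scheme version.
#' @return single character string.
#' @export
typingSchemeVersion <- function() .TYPING_SCHEME_VERSION

#' Atomic number of an element symbol
#' @param element character vector of element symbols (case-sensitive).
#' @return integer vector of atomic numbers.
#' @export
atomicNumber <- function(element) {
  z <- match(element, .ELEMENTS)
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  z
}

#' Assign the six-digit ABBCDD atom-type code to one atom
#'
#' The code encodes the element plus a one-bond summary of the local
#' environment, so chemically distinct atoms of the same element receive
#' distinct types while the total number of types stays small:
#'
#' * `A` — formal-charge class: 1 neutral, 2 cation, 0 anion.
#' * `BB` — atomic number, zero-padded to two digits (so only elements with
#'   atomic number <= 99 are supported).
#' * `C` — environment class: 0 aromatic, 1 saturated (all single bonds),
#'   2 doubly bonded (sp2-like), 3 triply bonded (sp-like).
#' * `DD` — 10 x (number of bonded heteroatoms, capped at 9) + (number of
#'   bonded heavy atoms, capped at 9).
#'
#' The code is a pure function of the atom and its bonded neighbourhood: it
#' does not depend on atom numbering, so automorphic atoms always receive
#' identical codes. An ether oxygen, for instance, types as 108102 (neutral,
#' Z = 8, saturated, no bonded heteroatoms, two heavy neighbours).
#'
#' @param molecule a [MolecularGraph-class].
#' @param atomIndex 1-based heavy-atom index.
#' @return atom-type code as a 6-character string (zero-padded).
#' @examples
#' m <- molecularGraph(c("C", "O", "C"),
#'                     data.frame(from = c(1, 2), to = c(2, 3), order = 1))
#' assignAtomType(m, 2)  # "108102"
#' @export
assignAtomType <- function(molecule, atomIndex) {
  a <- molecule@atoms
  n <- nrow(a)
  atomIndex <- as.integer(atomIndex)
  if (length(atomIndex) != 1L || is.na(atomIndex) || atomIndex < 1L ||
      atomIndex > n)
    stop("atomIndex out of range: ", atomIndex)
  typeAllAtoms(molecule)[atomIndex]
}

#' Type every heavy atom of a molecule
#'
#' @param molecule a [MolecularGraph-class].
#' @return character vector of atom-type codes, one per atom, in atom-index
#'   order.
#' @seealso [assignAtomType()] for the code semantics.
#' @export
typeAllAtoms <- function(molecule) {
  a <- molecule@atoms
  b <- molecule@bonds
  n <- nrow(a)
  z <- atomicNumber(a$element)
  if (any(z > 99L))
    stop("unsupported element (atomic number > 99): ",
         paste(unique(a$element[z > 99L]), collapse = ", "))

  charge_class <- ifelse(a$charge > 0L, 2L, ifelse(a$charge < 0L, 0L, 1L))

  max_order <- integer(n)           # highest bond order incident to atom
  n_heavy <- integer(n)             # bonded heavy-atom count
  n_hetero <- integer(n)            # bonded heteroatom (not C, not H) count
  if (nrow(b) > 0L) {
    hetero <- !(a$element %in% "C")
    for (k in seq_len(nrow(b))) {
      i <- b$from[k]; j <- b$to[k]; o <- b$order[k]
      max_order[i] <- max(max_order[i], o)
      max_order[j] <- max(max_order[j], o)
      n_heavy[i] <- n_heavy[i] + 1L
      n_heavy[j] <- n_heavy[j] + 1L
      if (hetero[j]) n_hetero[i] <- n_hetero[i] + 1L
      if (hetero[i]) n_hetero[j] <- n_hetero[j] + 1L
    }
  }
  env_class <- ifelse(a$aromatic, 0L,
                      ifelse(max_order >= 3L, 3L,
                             ifelse(max_order == 2L, 2L, 1L)))
  dd <- 10L * pmin(n_hetero, 9L) + pmin(n_heavy, 9L)
  sprintf("%1d%02d%1d%02d", charge_class, z, env_class, dd)
}
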