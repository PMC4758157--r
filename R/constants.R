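# Shared reference tables: van der Waals radii, per-residue maximum SASA,
# canonical heavy-atom compositions, amino-acid code maps.

#' Bondi van der Waals radii for protein heavy atoms (and H), in Angstroms
#'
#' Single published radii set used by default for the contact criterion.
#' A different table can be supplied to the contact functions via
#' `radii`; the criterion itself is radius-table-agnostic.
#'
#' @return Named numeric vector, element symbol -> radius (A).
#' @export
#' @examples
#' vdw_radii_bondi()[["C"]]
vdw_radii_bondi <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

#' Theoretical maximum solvent accessibility per residue type
#'
#' Tien et al. (2013) theoretical maxima, in A^2, used as the denominator
#' for relative solvent accessibility when classifying residues as buried
#' (<= 5 % exposure by default).
#'
#' @return Named numeric vector, three-letter residue code -> max SASA (A^2).
#' @export
max_sasa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

# three-letter <-> one-letter maps
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V")

aa3_to_1 <- function(x) {
  out <- .aa1[match(x, .aa3)]
  if (anyNA(out)) stop("unknown residue type(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

aa1_to_3 <- function(x) {
  out <- .aa3[match(x, .aa1)]
  if (anyNA(out)) stop("unknown residue letter(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# Canonical heavy side-chain atom names per residue type (PDB naming,
# backbone N/CA/C/O excluded). Order is proximal -> distal.
.side_chain_atoms <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.backbone_atoms <- c("N", "CA", "C", "O")

# element symbol from a standard amino-acid atom name
element_from_atom_name <- function(atom_name) {
  first <- substr(atom_name, 1L, 1L)
  ok <- first %in% c("C", "N", "O", "S", "H", "P")
  if (!all(ok)) stop("cannot infer element for atom name(s): ",
                     paste(unique(atom_name[!ok]), collapse = ", "))
  first
}

# all valid heavy-atom names (for role classification error checking)
.known_atom_names <- unique(c(.backbone_atoms, "OXT",
                              unlist(.side_chain_atoms, use.names = FALSE)))
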