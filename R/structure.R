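# ComplexStructure container and PDB I/O.
#
# A complex_structure holds one atom table for a (multi-chain) protein
# complex. Coordinates are in Angstroms in the PDB frame; residue numbering
# is 1-based and contiguous per chain, equal to the ungapped sequence
# position (enforced at construction).

#' Build a complex structure from an atom table
#'
#' @param atoms data.frame with columns `chain_id`, `residue_index`,
#'   `residue_type` (3-letter code), `atom_name`, `element`, `x`, `y`, `z`.
#' @param radii named vector of van der Waals radii per element; defaults to
#'   the Bondi heavy-atom set.
#' @param check if `TRUE` (default) enforce the container invariants:
#'   finite coordinates, positive radii, unique (chain, residue, atom) keys,
#'   contiguous 1-based residue numbering per chain.
#'
#' @return An object of class `complex_structure`: a list with `atoms`
#'   (the table, with a `vdw_radius` column added) and `chains` (ordered
#'   chain ids).
#' @export
complex_structure <- function(atoms, radii = vdw_radii_bondi(), check = TRUE) {
  needed <- c("chain_id", "residue_index", "residue_type", "atom_name",
              "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table missing column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, needed]
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_index <- as.integer(atoms$residue_index)

  r <- radii[atoms$element]
  if (anyNA(r)) {
    bad <- unique(atoms$atom_name[is.na(r)])
    stop("no van der Waals radius for atom(s): ", paste(bad, collapse = ", "))
  }
  atoms$vdw_radius <- as.numeric(r)

  if (check) {
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("non-finite atom coordinates")
    if (any(atoms$vdw_radius <= 0)) stop("non-positive van der Waals radius")
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    if (anyDuplicated(key))
      stop("duplicate (chain, residue, atom) records: ",
           key[anyDuplicated(key)])
    for (ch in unique(atoms$chain_id)) {
      idx <- sort(unique(atoms$residue_index[atoms$chain_id == ch]))
      if (!identical(idx, seq_along(idx)))
        stop("residue indices not contiguous 1-based in chain ", ch)
    }
  }
  structure(list(atoms = atoms, chains = unique(atoms$chain_id)),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  seqs <- chain_sequences(x)
  cat("complex_structure:", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s)\n")
  for (ch in x$chains)
    cat("  chain ", ch, ": ", nchar(seqs[[ch]]), " residues\n", sep = "")
  invisible(x)
}

#' Per-chain amino-acid sequences of a complex
#'
#' @param structure a `complex_structure`.
#' @return Named character vector of one-letter sequences, one per chain,
#'   in residue-index order.
#' @export
chain_sequences <- function(structure) {
  at <- structure$atoms
  out <- vapply(structure$chains, function(ch) {
    sub <- at[at$chain_id == ch, ]
    sub <- sub[!duplicated(sub$residue_index), ]
    sub <- sub[order(sub$residue_index), ]
    paste(aa3_to_1(sub$residue_type), collapse = "")
  }, character(1))
  names(out) <- structure$chains
  out
}

#' Read a protein complex from a PDB file
#'
#' ATOM records are parsed with bio3d; HETATM records (ligands, waters) are
#' dropped, as are protein chains shorter than `min_chain_length` residues.
#' Residues are renumbered 1-based and contiguous per chain so that the
#' structure numbering equals the ungapped sequence position. Files using
#' insertion codes are rejected.
#'
#' @param path PDB file.
#' @param min_chain_length chains with fewer residues are excluded
#'   (default 50).
#' @param radii named element -> radius table (A).
#' @return A [complex_structure()].
#' @export
read_complex_pdb <- function(path, min_chain_length = 50,
                             radii = vdw_radii_bondi()) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("PDB files with insertion codes are not supported: ", path)

  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- element_from_atom_name(at$elety)
  } else {
    blank <- is.na(element) | element == ""
    element[blank] <- element_from_atom_name(at$elety[blank])
    element <- toupper(element)
  }

  atoms <- data.frame(chain_id = as.character(at$chain),
                      residue_index = as.integer(at$resno),
                      residue_type = at$resid,
                      atom_name = at$elety,
                      element = element,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)

  keep <- vapply(split(seq_len(nrow(atoms)), atoms$chain_id), function(i) {
    length(unique(atoms$residue_index[i])) >= min_chain_length
  }, logical(1))
  atoms <- atoms[atoms$chain_id %in% names(keep)[keep], , drop = FALSE]
  if (!nrow(atoms))
    stop("no chain of length >= ", min_chain_length, " in ", path)

  # renumber contiguous 1-based per chain, preserving order of appearance
  for (ch in unique(atoms$chain_id)) {
    i <- atoms$chain_id == ch
    old <- atoms$residue_index[i]
    atoms$residue_index[i] <- match(old, unique(old))
  }
  complex_structure(atoms, radii = radii)
}

#' Write a complex structure as a minimal PDB file
#'
#' Emits ATOM records only (chain ids and 1-based residue numbering as held
#' in the structure), via bio3d. Output is byte-deterministic for a given
#' structure.
#'
#' @param structure a `complex_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(structure, path) {
  at <- structure$atoms
  o <- order(match(at$chain_id, structure$chains), at$residue_index,
             match(at$atom_name, c(.backbone_atoms, "OXT",
                                   unlist(.side_chain_atoms))))
  at <- at[o, ]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$residue_index,
                   resid = at$residue_type,
                   chain = at$chain_id,
                   eleno = seq_len(nrow(at)),
                   elety = at$atom_name,
                   elesy = at$element,
                   end = TRUE)
  invisible(path)
}
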