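# Geometric interface detection: van der Waals contact criterion, interface
# residue sets, atom role classification.
#
# Two atoms on different chains are "in contact" when their distance is
# strictly less than the sum of their van der Waals radii plus a margin
# (0.5 A by default). Pairs closer than the radii sum alone are clashes and
# are still counted as contacts, so side-chain placement error in modelled
# structures cannot remove an interface residue.

#' Detect inter-chain atom contacts
#'
#' Returns every atom pair (one atom per chain) with distance
#' `< r_a + r_b + margin`. Pairs with distance `< r_a + r_b` are flagged
#' `clash = TRUE` and included. The default search uses a cell list (grid
#' binning at the maximum contact threshold) for expected linear time;
#' `method = "brute"` runs the all-pairs scan that defines correctness.
#'
#' @param structure a [complex_structure()].
#' @param chain_a,chain_b chain identifiers (order does not affect the
#'   resulting pair set).
#' @param margin contact margin in Angstroms (default 0.5, must be >= 0).
#' @param method "cell" (spatial index, default) or "brute" (all pairs).
#' @return data.frame with one row per contacting pair: `chain_a`,
#'   `residue_a`, `atom_a`, `chain_b`, `residue_b`, `atom_b`, `distance`,
#'   `clash`; the chain pair is stored in attribute `chain_pair`.
#' @export
detect_atom_contacts <- function(structure, chain_a, chain_b, margin = 0.5,
                                 method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(margin >= 0)
  at <- structure$atoms
  if (!chain_a %in% at$chain_id) stop("chain not in structure: ", chain_a)
  if (!chain_b %in% at$chain_id) stop("chain not in structure: ", chain_b)
  A <- at[at$chain_id == chain_a, , drop = FALSE]
  B <- at[at$chain_id == chain_b, , drop = FALSE]

  if (method == "brute") {
    ia <- rep(seq_len(nrow(A)), each = nrow(B))
    ib <- rep(seq_len(nrow(B)), times = nrow(A))
  } else {
    cell <- 2 * max(A$vdw_radius, B$vdw_radius) + margin
    keyfun <- function(df) paste(floor(df$x / cell), floor(df$y / cell),
                                 floor(df$z / cell), sep = ",")
    bx <- floor(B$x / cell); by <- floor(B$y / cell); bz <- floor(B$z / cell)
    bidx <- split(seq_len(nrow(B)), paste(bx, by, bz, sep = ","))
    ax <- floor(A$x / cell); ay <- floor(A$y / cell); az <- floor(A$z / cell)
    ia <- integer(0); ib <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      hits <- bidx[paste(ax + dx, ay + dy, az + dz, sep = ",")]
      n <- lengths(hits)
      if (any(n > 0)) {
        ia <- c(ia, rep(seq_len(nrow(A)), n))
        ib <- c(ib, unlist(hits, use.names = FALSE))
      }
    }
  }

  d2 <- (A$x[ia] - B$x[ib])^2 + (A$y[ia] - B$y[ib])^2 + (A$z[ia] - B$z[ib])^2
  thr <- A$vdw_radius[ia] + B$vdw_radius[ib] + margin
  keep <- d2 < thr^2
  ia <- ia[keep]; ib <- ib[keep]
  d <- sqrt(d2[keep])

  out <- data.frame(chain_a = rep(chain_a, length(ia)),
                    residue_a = A$residue_index[ia],
                    atom_a = A$atom_name[ia],
                    chain_b = rep(chain_b, length(ib)),
                    residue_b = B$residue_index[ib],
                    atom_b = B$atom_name[ib],
                    distance = d,
                    clash = d < (A$vdw_radius[ia] + B$vdw_radius[ib]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue_a, out$atom_a, out$residue_b, out$atom_b), ]
  rownames(out) <- NULL
  attr(out, "chain_pair") <- c(chain_a, chain_b)
  attr(out, "margin") <- margin
  out
}

#' Derive the binding interface from a contact list
#'
#' All residues owning at least one contacting atom form the interface;
#' clash contacts contribute residues exactly like ordinary contacts.
#'
#' @param contacts output of [detect_atom_contacts()] (all rows must share
#'   one chain pair).
#' @return An object of class `ppi_interface`: list with `chain_pair`,
#'   `residues_a`, `residues_b` (sorted residue indices) and the `contacts`
#'   table itself.
#' @export
identify_interface <- function(contacts) {
  if (nrow(contacts)) {
    pairs <- unique(paste(contacts$chain_a, contacts$chain_b))
    if (length(pairs) > 1)
      stop("contacts span multiple chain pairs: ",
           paste(pairs, collapse = "; "))
    chain_pair <- c(contacts$chain_a[1], contacts$chain_b[1])
  } else {
    chain_pair <- attr(contacts, "chain_pair")
    if (is.null(chain_pair)) chain_pair <- c(NA_character_, NA_character_)
  }
  structure(list(chain_pair = chain_pair,
                 residues_a = sort(unique(contacts$residue_a)),
                 residues_b = sort(unique(contacts$residue_b)),
                 contacts = contacts),
            class = "ppi_interface")
}

#' @export
print.ppi_interface <- function(x, ...) {
  cat("ppi_interface ", x$chain_pair[1], "-", x$chain_pair[2], ": ",
      length(x$residues_a), "+", length(x$residues_b), " residues, ",
      nrow(x$contacts), " atom contacts (", sum(x$contacts$clash),
      " clashes)\n", sep = "")
  invisible(x)
}

#' Write an interface as a TSV contact table
#'
#' @param interface a `ppi_interface`.
#' @param path output TSV (columns chain_a, res_a, chain_b, res_b, distance,
#'   clash).
#' @export
write_interface_tsv <- function(interface, path) {
  ct <- interface$contacts
  out <- data.frame(chain_a = ct$chain_a, res_a = ct$residue_a,
                    chain_b = ct$chain_b, res_b = ct$residue_b,
                    distance = round(ct$distance, 3), clash = ct$clash)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a residue as buried or exposed from its relative accessibility
#'
#' @param residue_sasa observed solvent-accessible surface area (A^2),
#'   must be non-negative.
#' @param max_sasa_for_type theoretical maximum SASA for the residue type
#'   (A^2), see [max_sasa_reference()].
#' @param threshold relative-accessibility cutoff; at or below it the
#'   residue is buried (default 0.05, i.e. <= 5 % exposure).
#' @return `"buried"` or `"exposed"`.
#' @export
classify_buried <- function(residue_sasa, max_sasa_for_type,
                            threshold = 0.05) {
  if (any(residue_sasa < 0)) stop("negative SASA")
  stopifnot(all(max_sasa_for_type > 0))
  ifelse(residue_sasa / max_sasa_for_type <= threshold, "buried", "exposed")
}

#' Classify the structural role of a protein atom by its PDB name
#'
#' Backbone atoms (N, CA, C, O, OXT and backbone hydrogens) are
#' `main_chain`; the beta carbon is `c_beta`; hydrogens on the beta carbon
#' are `h_beta`; every other (side-chain) atom is `side_chain_specific` --
#' the atoms whose identity distinguishes one residue type from another.
#'
#' @param atom_name PDB atom name(s), standard amino-acid naming.
#' @return Character vector of roles.
#' @export
classify_atom_role <- function(atom_name) {
  main <- c(.backbone_atoms, "OXT", "H", "H1", "H2", "H3", "HN",
            "HA", "HA2", "HA3")
  role <- rep(NA_character_, length(atom_name))
  role[atom_name %in% main] <- "main_chain"
  role[atom_name == "CB"] <- "c_beta"
  role[grepl("^[0-9]?HB[0-9]?$", atom_name)] <- "h_beta"
  side <- is.na(role) &
    (atom_name %in% .known_atom_names | grepl("^[0-9]?H[A-Z][0-9]*$", atom_name))
  role[side] <- "side_chain_specific"
  if (anyNA(role))
    stop("unknown atom name(s): ",
         paste(unique(atom_name[is.na(role)]), collapse = ", "))
  role
}
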