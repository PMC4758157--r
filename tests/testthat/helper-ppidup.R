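# Shared fixture builders and independent oracles.

# minimal two-chain structure: one atom per residue at given coordinates
two_atom_structure <- function(d, element = c("C", "C"),
                               atom = c("CB", "CB")) {
  complex_structure(data.frame(
    chain_id = c("A", "B"), residue_index = 1L,
    residue_type = "ALA", atom_name = atom, element = element,
    x = c(0, d), y = 0, z = 0))
}

# brute-force all-pairs contact oracle, independent of the package path
brute_contact_pairs <- function(structure, chain_a, chain_b, margin = 0.5) {
  at <- structure$atoms
  A <- at[at$chain_id == chain_a, ]
  B <- at[at$chain_id == chain_b, ]
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((unlist(A[i, c("x", "y", "z")]) -
                     unlist(B[j, c("x", "y", "z")]))^2))
    if (d < A$vdw_radius[i] + B$vdw_radius[j] + margin)
      out[[length(out) + 1]] <- paste(A$residue_index[i], A$atom_name[i],
                                      B$residue_index[j], B$atom_name[j])
  }
  sort(unlist(out))
}

contact_keys <- function(contacts) {
  sort(paste(contacts$residue_a, contacts$atom_a,
             contacts$residue_b, contacts$atom_b))
}

# evidence records for a pair of genes and explicit partner sets, each edge
# supported by two studies so the MC filter keeps it
records_for_partners <- function(gene_a, partners_a, gene_b, partners_b) {
  edges <- rbind(
    if (length(partners_a)) data.frame(protein_a = gene_a,
                                       protein_b = partners_a),
    if (length(partners_b)) data.frame(protein_a = gene_b,
                                       protein_b = partners_b))
  if (is.null(edges)) return(data.frame(protein_a = character(0),
                                        protein_b = character(0),
                                        study_id = character(0)))
  data.frame(protein_a = rep(edges$protein_a, each = 2),
             protein_b = rep(edges$protein_b, each = 2),
             study_id = rep(c("S1", "S2"), nrow(edges)))
}

# independent pathway-counting oracle: recursively enumerate orderings of
# the differing codon positions, drop pathways through stops, average N/S
oracle_pathway_counts <- function(from, to) {
  gc <- Biostrings::GENETIC_CODE
  diffpos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  paths <- list()
  recurse <- function(cur, remaining, n, s, stopped) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(n, s, stopped)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      hit_stop <- gc[[nxt]] == "*" && nxt != to
      syn <- gc[[nxt]] == gc[[cur]]
      recurse(nxt, setdiff(remaining, p),
              n + !syn, s + syn, stopped || hit_stop)
    }
  }
  if (!length(diffpos)) return(c(N = 0, S = 0))
  recurse(from, diffpos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(N = mean(m[ok, 1]), S = mean(m[ok, 2]))
}

# exhaustive minimal codon-change count over internal labelings (states
# restricted to leaf codons, valid for unit-cost parsimony)
oracle_parsimony_changes <- function(tree, leaf_codons) {
  ntip <- ape::Ntip(tree)
  states <- unique(leaf_codons)
  internals <- ntip + seq_len(tree$Nnode)
  grid <- do.call(expand.grid,
                  c(rep(list(states), length(internals)),
                    stringsAsFactors = FALSE))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(leaf_codons, unlist(grid[g, ], use.names = FALSE))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# changes implied by a parsimony assignment
assignment_changes <- function(anc, site) {
  s <- anc$states[, site]
  sum(s[anc$tree$edge[, 1]] != s[anc$tree$edge[, 2]])
}
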