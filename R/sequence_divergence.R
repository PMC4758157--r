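# Interface-aware substitution accounting on paralogue alignments:
# mapping interfaces onto alignment columns, region substitution counts,
# the relative interface substitution rate with its >2x exclusion filter,
# pairwise divergence (protein and Nei-Gojobori Ka/Ks), the interface/
# interaction 2x2 classification, and interface substitution matrices.

#' Label alignment columns as interface or non-interface
#'
#' A column is an interface column when either member's residue at that
#' column (by ungapped sequence position) lies in an identified interface.
#' Non-interface columns include both core and surface residues.
#'
#' @param aligned_a,aligned_b gapped amino-acid strings of equal length.
#' @param sites_a,sites_b interface residue indices (1-based ungapped
#'   positions) of each member.
#' @return Character vector (length = alignment columns) of
#'   `"interface"` / `"non_interface"`.
#' @export
map_interface_to_alignment <- function(aligned_a, aligned_b, sites_a,
                                       sites_b = integer(0)) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  if (length(sites_a) && max(sites_a) > max(pos_a, 0))
    stop("interface residue index beyond sequence length (member A)")
  if (length(sites_b) && max(sites_b) > max(pos_b, 0))
    stop("interface residue index beyond sequence length (member B)")
  hit_a <- a != "-" & pos_a %in% sites_a
  hit_b <- b != "-" & pos_b %in% sites_b
  ifelse(hit_a | hit_b, "interface", "non_interface")
}

#' Count substitutions and gaps per alignment region
#'
#' @param aligned_a,aligned_b gapped amino-acid strings.
#' @param columns region label per column, from
#'   [map_interface_to_alignment()].
#' @return data.frame with one row per region (`interface`,
#'   `non_interface`): `n_sites` (columns), `n_subs` (amino-acid
#'   mismatches, gap columns excluded), `n_gaps` (columns with a gap in
#'   either member).
#' @export
count_substitutions <- function(aligned_a, aligned_b, columns) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  if (length(columns) != length(a))
    stop("column labels do not match alignment length")
  gap <- a == "-" | b == "-"
  sub <- !gap & a != b
  out <- lapply(c("interface", "non_interface"), function(reg) {
    i <- columns == reg
    data.frame(region = reg, n_sites = sum(i), n_subs = sum(sub & i),
               n_gaps = sum(gap & i))
  })
  do.call(rbind, out)
}

#' Relative interface substitution rate with the twofold exclusion filter
#'
#' Ratio of per-site substitution rates: (interface substitutions /
#' interface comparable sites) over the same quantity outside interfaces.
#' Gap columns are excluded from both numerators and site totals. Pairs
#' whose interfaces change more than `cap` times faster than the rest of
#' the protein are flagged for exclusion as likely erroneous rate
#' estimates.
#'
#' @param counts output of [count_substitutions()].
#' @param cap exclusion threshold on the ratio (default 2).
#' @return List with `ratio` (NA when the non-interface rate is 0),
#'   `rate_interface`, `rate_non_interface`, `excluded` (TRUE when ratio >
#'   cap), `reason`.
#' @export
relative_interface_rate <- function(counts, cap = 2) {
  g <- function(reg, col) counts[counts$region == reg, col]
  comp_i <- g("interface", "n_sites") - g("interface", "n_gaps")
  comp_n <- g("non_interface", "n_sites") - g("non_interface", "n_gaps")
  if (comp_i <= 0 || comp_n <= 0) {
    return(list(ratio = NA_real_, rate_interface = NA_real_,
                rate_non_interface = NA_real_, excluded = TRUE,
                reason = "zero comparable sites in a region"))
  }
  ri <- g("interface", "n_subs") / comp_i
  rn <- g("non_interface", "n_subs") / comp_n
  if (rn == 0) {
    return(list(ratio = NA_real_, rate_interface = ri,
                rate_non_interface = 0, excluded = FALSE,
                reason = "undefined: zero non-interface rate"))
  }
  ratio <- ri / rn
  list(ratio = ratio, rate_interface = ri, rate_non_interface = rn,
       excluded = ratio > cap,
       reason = if (ratio > cap) sprintf("ratio %.3f exceeds cap %g",
                                         ratio, cap) else NA_character_)
}

#' Pairwise divergence of a duplicate pair
#'
#' Protein divergence (mismatches over gap-free columns) and, when codon
#' sequences are given, Nei-Gojobori Ka and Ks by pathway-averaged
#' counting.
#'
#' @param aligned_a,aligned_b gapped amino-acid strings.
#' @param codon_a,codon_b optional aligned coding sequences (gap codon
#'   `---`).
#' @return List with `protein_divergence`, `n_compared`, and (when codons
#'   are given) the [ng_kaks()] fields.
#' @export
pairwise_divergence <- function(aligned_a, aligned_b,
                                codon_a = NULL, codon_b = NULL) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  ok <- a != "-" & b != "-"
  out <- list(protein_divergence = if (any(ok)) mean(a[ok] != b[ok])
              else NA_real_,
              n_compared = sum(ok))
  if (!is.null(codon_a) && !is.null(codon_b))
    out <- c(out, ng_kaks(codon_a, codon_b))
  out
}

#' Classify a duplicate pair into the interface x interaction contingency
#'
#' Interface status is `diverged` when any interface column carries a
#' substitution or (by default) a gap; interaction status is `diverged`
#' when the members' partner sets differ (SIR < 1) on the given network.
#'
#' @param pair_id identifier for the pair.
#' @param aligned_a,aligned_b gapped amino-acid strings.
#' @param columns region label per column.
#' @param gene_a,gene_b network identifiers of the two members.
#' @param network a `ppi_network`.
#' @param gaps_diverge count interface gap columns as divergence
#'   (default TRUE).
#' @return List of class `divergence_call` with `pair_id`,
#'   `interface_status`, `interaction_status`, `sir`; `NULL` when a member
#'   is absent from the network (pair excluded).
#' @export
classify_pair_divergence <- function(pair_id, aligned_a, aligned_b, columns,
                                     gene_a, gene_b, network,
                                     gaps_diverge = TRUE) {
  sir <- compute_sir(gene_a, gene_b, network, strict = FALSE)
  if (is.null(sir)) return(NULL)
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  i <- columns == "interface"
  gap <- a == "-" | b == "-"
  sub <- !gap & a != b
  hit <- any(sub[i]) || (gaps_diverge && any(gap[i]))
  structure(list(pair_id = pair_id,
                 interface_status = if (hit) "diverged" else "conserved",
                 interaction_status = if (sir$sir < 1) "diverged"
                 else "conserved",
                 sir = sir$sir),
            class = "divergence_call")
}

#' Tabulate divergence calls as the 2x2 interface x interaction table
#'
#' @param calls list of `divergence_call` objects (NULLs dropped).
#' @return 2x2 integer matrix, rows = interface status, columns =
#'   interaction status.
#' @export
divergence_table <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  lv <- c("conserved", "diverged")
  m <- matrix(0L, 2, 2, dimnames = list(interface = lv, interaction = lv))
  for (cl in calls)
    m[cl$interface_status, cl$interaction_status] <-
      m[cl$interface_status, cl$interaction_status] + 1L
  m
}

#' Interface substitution matrices by interaction status
#'
#' Undirected 21 x 21 counts (20 amino acids + gap) of the residue pairs
#' observed at differing interface columns, split by whether the pair's
#' physical interactions are conserved or diverged. Substitutions are
#' undirected (the count matrices are symmetric); per-cell proportions
#' across the two statuses are returned for non-empty cells.
#'
#' @param pair_data list; each element a list with `aligned_a`,
#'   `aligned_b`, `columns` (region labels) and `call` (a
#'   `divergence_call`).
#' @return Object of class `substitution_matrix`: list with `conserved`
#'   and `diverged` count matrices and `proportions` (same shape;
#'   conserved share of each non-empty cell, NA where empty).
#' @export
build_substitution_matrix <- function(pair_data) {
  syms <- c(.aa1, "-")
  empty <- matrix(0L, 21, 21, dimnames = list(syms, syms))
  mats <- list(conserved = empty, diverged = empty)
  for (pd in pair_data) {
    if (is.null(pd$call)) next
    status <- pd$call$interaction_status
    a <- strsplit(pd$aligned_a, "")[[1]]
    b <- strsplit(pd$aligned_b, "")[[1]]
    i <- which(pd$columns == "interface" & a != b)
    for (k in i) {
      if (!a[k] %in% syms) stop("non-standard residue letter: ", a[k])
      if (!b[k] %in% syms) stop("non-standard residue letter: ", b[k])
      mats[[status]][a[k], b[k]] <- mats[[status]][a[k], b[k]] + 1L
      mats[[status]][b[k], a[k]] <- mats[[status]][b[k], a[k]] + 1L
    }
  }
  tot <- mats$conserved + mats$diverged
  prop <- ifelse(tot > 0, mats$conserved / tot, NA_real_)
  structure(list(conserved = mats$conserved, diverged = mats$diverged,
                 proportions = prop),
            class = "substitution_matrix")
}

#' Total substitutions recorded in a substitution matrix
#'
#' Each undirected substitution is stored symmetrically, so the total is
#' half the matrix sum.
#'
#' @param m a `substitution_matrix`.
#' @param status `"conserved"`, `"diverged"` or `"both"`.
#' @return Integer count.
#' @export
substitution_matrix_total <- function(m, status = c("both", "conserved",
                                                    "diverged")) {
  status <- match.arg(status)
  s <- switch(status,
              both = sum(m$conserved) + sum(m$diverged),
              conserved = sum(m$conserved),
              diverged = sum(m$diverged))
  as.integer(s / 2)
}

#' Write a substitution matrix as a long-format TSV
#'
#' @param m a `substitution_matrix`.
#' @param path output TSV (res_a, res_b, status, count, proportion).
#' @export
write_substitution_matrix_tsv <- function(m, path) {
  syms <- rownames(m$conserved)
  rows <- list()
  for (status in c("conserved", "diverged")) {
    mm <- m[[status]]
    idx <- which(upper.tri(mm, diag = TRUE) & (m$conserved + m$diverged) > 0,
                 arr.ind = TRUE)
    if (nrow(idx)) {
      pr <- m$proportions[idx]
      if (status == "diverged") pr <- 1 - pr
      rows[[status]] <- data.frame(res_a = syms[idx[, 1]],
                                   res_b = syms[idx[, 2]],
                                   status = status, count = mm[idx],
                                   proportion = pr)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(res_a = character(0), res_b = character(0),
                      status = character(0), count = integer(0),
                      proportion = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
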