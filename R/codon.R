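# Codon-level utilities: translation, Nei-Gojobori site counting and
# pathway-averaged substitution counting, pairwise Ka/Ks.
#
# The genetic code is the universal code as shipped by Biostrings. Counting
# conventions: mutations to stop codons count as nonsynonymous for site
# counting; substitution pathways passing through a stop codon are excluded
# from pathway averaging (unless every pathway is blocked, in which case all
# pathways are used with the stop treated as a distinct residue state).

.genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate a vector of codons
#'
#' @param codons character vector of 3-letter nucleotide codons (T alphabet).
#' @return Character vector of one-letter amino acids (`*` for stop).
#' @export
translate_codons <- function(codons) {
  gc <- .genetic_code()
  aa <- unname(gc[toupper(codons)])
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}

#' All 61 sense codons, lexicographic order
#' @return Character vector.
#' @export
sense_codons <- function() {
  gc <- .genetic_code()
  sort(names(gc)[gc != "*"])
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' For each codon position, the fraction of the three possible single
#' nucleotide changes that are synonymous contributes to the synonymous
#' site count; the remainder (including changes to stop codons) are
#' nonsynonymous sites. Sites sum to 3 per codon.
#'
#' @param codon a single sense codon.
#' @return Named numeric vector `c(syn = , nonsyn = )`.
#' @export
ng_site_counts <- function(codon) {
  codon <- toupper(codon)
  aa0 <- translate_codons(codon)
  if (aa0 == "*") stop("stop codon has no site counts: ", codon)
  nts <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (translate_codons(alt) == aa0) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# N/S substitution counts between two codons, averaged over all shortest
# mutational pathways (orderings of the differing positions); pathways that
# pass through a stop codon are dropped. Returns c(N =, S =).
ng_pathway_counts <- function(codon_from, codon_to) {
  codon_from <- toupper(codon_from); codon_to <- toupper(codon_to)
  diffpos <- which(strsplit(codon_from, "")[[1]] != strsplit(codon_to, "")[[1]])
  k <- length(diffpos)
  if (k == 0) return(c(N = 0, S = 0))
  perms <- list(
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )[[k]]

  count_path <- function(ord, allow_stop) {
    cur <- codon_from
    n <- 0; s <- 0
    for (p in diffpos[ord]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_to, p, p)
      aa_cur <- translate_codons(cur); aa_nxt <- translate_codons(nxt)
      if (!allow_stop && aa_nxt == "*" && nxt != codon_to) return(NULL)
      if (aa_cur == aa_nxt) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(N = n, S = s)
  }

  paths <- Filter(Negate(is.null), lapply(perms, count_path, allow_stop = FALSE))
  if (!length(paths))
    paths <- lapply(perms, count_path, allow_stop = TRUE)
  m <- do.call(rbind, paths)
  colMeans(m)
}

#' Pairwise Ka and Ks by Nei-Gojobori counting
#'
#' Standard pathway-averaged counting on a pair of aligned coding sequences:
#' synonymous/nonsynonymous sites averaged over the two sequences,
#' substitutions averaged over shortest mutational pathways per codon, and
#' Jukes-Cantor multiple-hit correction of the resulting proportions.
#' Codon columns containing a gap or an ambiguous base are skipped.
#'
#' @param cds_a,cds_b aligned nucleotide strings (equal length, length a
#'   multiple of 3).
#' @return List with `ka`, `ks`, `pn`, `ps` (uncorrected proportions),
#'   `n_sites`, `s_sites`, `n_subs`, `s_subs`.
#' @export
ng_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("coding sequences differ in length")
  if (nchar(cds_a) %% 3 != 0) stop("coding length not a multiple of 3")
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  ok <- grepl("^[ACGTacgt]{3}$", ca) & grepl("^[ACGTacgt]{3}$", cb)
  ca <- toupper(ca[ok]); cb <- toupper(cb[ok])
  keep <- translate_codons(ca) != "*" & translate_codons(cb) != "*"
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop("no comparable codons")

  sites_a <- vapply(ca, ng_site_counts, numeric(2))
  sites_b <- vapply(cb, ng_site_counts, numeric(2))
  s_sites <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  n_sites <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2

  subs <- mapply(function(a, b) ng_pathway_counts(a, b), ca, cb)
  n_subs <- sum(subs["N", ]); s_subs <- sum(subs["S", ])

  pn <- n_subs / n_sites
  ps <- s_subs / s_sites
  # Jukes-Cantor multiple-hit correction; saturated proportions (p >= 3/4,
  # possible on very short sequences) are reported as Inf
  jc <- function(p) {
    if (p >= 0.75) return(Inf)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  list(ka = jc(pn), ks = jc(ps), pn = pn, ps = ps,
       n_sites = n_sites, s_sites = s_sites,
       n_subs = n_subs, s_subs = s_subs)
}

# split a nucleotide string into codons
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(x, seq(1, n, 3), seq(3, n, 3))
}
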