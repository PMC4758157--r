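# SLAC-style per-site selection classification on codon alignments:
# Fitch parsimony ancestral codons, per-branch substitution counting
# decomposed into single-nucleotide steps, expected site counts by
# Nei-Gojobori, a two-tailed binomial test per column, and group
# comparisons (Kruskal-Wallis, pairwise Mann-Whitney, Benjamini-Hochberg).

.pkg_cache <- new.env(parent = emptyenv())

# cached NG site counts per sense codon (61 x 2 matrix)
.ng_sites_table <- function() {
  if (is.null(.pkg_cache$ng_sites)) {
    cods <- sense_codons()
    .pkg_cache$ng_sites <- t(vapply(cods, ng_site_counts, numeric(2)))
  }
  .pkg_cache$ng_sites
}

# cached pathway counts between two codons
.ng_pathway_cached <- function(from, to) {
  key <- paste(from, to)
  v <- .pkg_cache[[key]]
  if (is.null(v)) {
    v <- ng_pathway_counts(from, to)
    assign(key, v, envir = .pkg_cache)
  }
  v
}

# normalise a tree argument (phylo or Newick string) to a rooted binary
# phylo; polytomies resolved deterministically in input order.
prepare_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                     error = function(e) NULL)
    if (is.null(tree)) stop("invalid Newick tree")
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo or Newick string")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  tree
}

#' Fitch parsimony ancestral codons
#'
#' Assigns a codon to every internal node of the tree at every alignment
#' column by Fitch parsimony over the 64 codon states, with ties broken by
#' codon lexicographic order (bottom-up: intersection where non-empty, else
#' union; top-down: keep the parent's codon when admissible, else the
#' lexicographically smallest admissible codon).
#'
#' @param tree a rooted tree (`phylo` or Newick string); polytomies are
#'   resolved deterministically.
#' @param alignment named character vector of equal-length codon strings,
#'   names matching the tree's tip labels.
#' @return List with `tree` (the prepared binary tree), `states` (matrix
#'   nodes x sites of codons, tips first in tip order, then internal nodes
#'   in ape numbering) and `n_sites`.
#' @export
parsimony_ancestral_codons <- function(tree, alignment) {
  tree <- prepare_tree(tree)
  missing <- setdiff(tree$tip.label, names(alignment))
  if (length(missing))
    stop("alignment missing taxa: ", paste(missing, collapse = ", "))
  aln <- alignment[tree$tip.label]
  lens <- unique(nchar(aln))
  if (length(lens) != 1) stop("alignment sequences differ in length")
  if (lens %% 3 != 0) stop("alignment length not a multiple of 3")
  n_sites <- lens / 3
  tip_codons <- matrix(unlist(lapply(aln, split_codons)),
                       nrow = length(aln), ncol = n_sites,
                       byrow = TRUE)  # tips x sites

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")$edge
  states <- matrix(NA_character_, ntip + nnode, n_sites)
  states[seq_len(ntip), ] <- tip_codons

  for (s in seq_len(n_sites)) {
    sets <- vector("list", ntip + nnode)
    for (i in seq_len(ntip)) sets[[i]] <- tip_codons[i, s]
    # bottom-up: children arrive before parents in postorder edges
    for (e in seq_len(nrow(post))) {
      par <- post[e, 1]; chd <- post[e, 2]
      sets[[par]] <- if (is.null(sets[[par]])) sets[[chd]] else {
        inter <- intersect(sets[[par]], sets[[chd]])
        if (length(inter)) inter else union(sets[[par]], sets[[chd]])
      }
    }
    # top-down assignment, preorder = reversed postorder edges
    root <- ntip + 1L
    states[root, s] <- min(sort(sets[[root]]))
    for (e in rev(seq_len(nrow(post)))) {
      par <- post[e, 1]; chd <- post[e, 2]
      if (chd <= ntip) next
      ps <- states[par, s]
      states[chd, s] <- if (ps %in% sets[[chd]]) ps else min(sort(sets[[chd]]))
    }
  }
  list(tree = tree, states = states, n_sites = n_sites)
}

#' Per-site substitution counts along the tree
#'
#' For one alignment column, codon differences on every branch are
#' decomposed into single-nucleotide steps averaged over shortest mutational
#' pathways and classified synonymous/nonsynonymous under the universal
#' code. Expected site counts EN and ES come from Nei-Gojobori site
#' counting averaged over the codons observed at the column (tips), scaled
#' by the total substitutions on the column so that EN + ES = N_obs +
#' S_obs.
#'
#' @param anc output of [parsimony_ancestral_codons()].
#' @param site column index (codon position).
#' @return Named numeric vector `c(N_obs, S_obs, EN, ES)`.
#' @export
count_site_substitutions <- function(anc, site) {
  tree <- anc$tree
  states <- anc$states[, site]
  ntip <- ape::Ntip(tree)
  aa <- translate_codons(states[seq_len(ntip)])
  if (any(aa == "*")) {
    bad <- which(aa == "*")[1]
    stop("stop codon at site ", site, " in taxon ", tree$tip.label[bad])
  }
  N <- 0; S <- 0
  for (e in seq_len(nrow(tree$edge))) {
    from <- states[tree$edge[e, 1]]
    to <- states[tree$edge[e, 2]]
    if (from != to) {
      v <- .ng_pathway_cached(from, to)
      N <- N + v[["N"]]; S <- S + v[["S"]]
    }
  }
  tab <- .ng_sites_table()
  obs <- states[seq_len(ntip)]
  mean_syn <- mean(tab[obs, "syn"])
  mean_nonsyn <- mean(tab[obs, "nonsyn"])
  tot <- N + S
  c(N_obs = N, S_obs = S,
    EN = mean_nonsyn / 3 * tot, ES = mean_syn / 3 * tot)
}

#' Classify a site's selection regime from observed and expected counts
#'
#' Two-tailed binomial test of the nonsynonymous count among all observed
#' substitutions, with success probability EN / (EN + ES). The two-tailed
#' p-value is min(1, 2 * min(lower tail, upper tail)). Below `alpha`, a
#' deficit of nonsynonymous change (N/EN < S/ES) is negative selection and
#' an excess positive selection; otherwise -- including columns with no
#' substitutions -- the site is neutral.
#'
#' @param N_obs,S_obs observed nonsynonymous/synonymous substitution
#'   counts.
#' @param EN,ES expected site counts (EN + ES > 0).
#' @param alpha significance cutoff (default 0.05).
#' @return List of class `site_selection`: `N_obs`, `S_obs`, `EN`, `ES`,
#'   `p_value`, `class` (`"negative"`, `"neutral"`, `"positive"`).
#' @export
classify_site <- function(N_obs, S_obs, EN, ES, alpha = 0.05) {
  if (N_obs < 0 || S_obs < 0 || EN < 0 || ES < 0) stop("negative counts")
  n <- N_obs + S_obs
  if (n == 0) {
    return(structure(list(N_obs = N_obs, S_obs = S_obs, EN = EN, ES = ES,
                          p_value = 1, class = "neutral"),
                     class = "site_selection"))
  }
  if (EN + ES <= 0) stop("EN + ES must be > 0")
  pr <- EN / (EN + ES)
  k <- round(N_obs)
  n_r <- round(n)
  lower <- stats::pbinom(k, n_r, pr)
  upper <- 1 - stats::pbinom(k - 1, n_r, pr)
  p <- min(1, 2 * min(lower, upper))
  cls <- "neutral"
  if (p < alpha) {
    cls <- if (N_obs / EN < S_obs / ES) "negative" else "positive"
  }
  structure(list(N_obs = N_obs, S_obs = S_obs, EN = EN, ES = ES,
                 p_value = p, class = cls),
            class = "site_selection")
}

#' Per-site selection scan of a codon alignment
#'
#' Runs [parsimony_ancestral_codons()], [count_site_substitutions()] and
#' [classify_site()] over every column.
#'
#' @param tree rooted tree (`phylo` or Newick string).
#' @param alignment named codon strings (see
#'   [parsimony_ancestral_codons()]).
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame with `site`, `N_obs`, `S_obs`, `EN`, `ES`,
#'   `p_value`, `class`.
#' @export
site_selection_scan <- function(tree, alignment, alpha = 0.05) {
  anc <- parsimony_ancestral_codons(tree, alignment)
  rows <- lapply(seq_len(anc$n_sites), function(s) {
    v <- count_site_substitutions(anc, s)
    cl <- classify_site(v[["N_obs"]], v[["S_obs"]], v[["EN"]], v[["ES"]],
                        alpha = alpha)
    data.frame(site = s, N_obs = v[["N_obs"]], S_obs = v[["S_obs"]],
               EN = v[["EN"]], ES = v[["ES"]], p_value = cl$p_value,
               class = cl$class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Selection-class proportions per region
#'
#' @param classes character vector of per-site classes (`negative` /
#'   `neutral` / `positive`).
#' @param regions region label per site (`interface` / `non_interface`).
#' @return data.frame per region with `n_sites` and the three class
#'   proportions; regions with zero sites are omitted (undefined
#'   proportions).
#' @export
region_selection_proportions <- function(classes, regions) {
  stopifnot(length(classes) == length(regions))
  out <- lapply(unique(regions), function(r) {
    cl <- classes[regions == r]
    if (!length(cl)) return(NULL)
    data.frame(region = r, n_sites = length(cl),
               prop_negative = mean(cl == "negative"),
               prop_neutral = mean(cl == "neutral"),
               prop_positive = mean(cl == "positive"))
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Compare selection proportions across groups
#'
#' Kruskal-Wallis across all groups, pairwise Mann-Whitney (Wilcoxon
#' rank-sum) tests for individual comparisons, Benjamini-Hochberg
#' adjustment of the pairwise p-values.
#'
#' @param groups named list of numeric vectors (one value per duplicate
#'   pair, e.g. its per-region proportion of negatively selected sites);
#'   at least two groups with two or more values each.
#' @return List with `kruskal` (statistic, p) and `pairwise` (data.frame
#'   group_a, group_b, statistic, p, p_adjusted).
#' @export
compare_selection_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values")
  kw <- stats::kruskal.test(groups)
  nm <- names(groups)
  combs <- utils::combn(seq_along(groups), 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    w <- suppressWarnings(stats::wilcox.test(groups[[i1]], groups[[i2]]))
    data.frame(group_a = nm[i1], group_b = nm[i2],
               statistic = unname(w$statistic), p = w$p.value)
  })
  pw <- do.call(rbind, rows)
  pw$p_adjusted <- stats::p.adjust(pw$p, method = "BH")
  list(kruskal = list(statistic = unname(kw$statistic), p = kw$p.value),
       pairwise = pw)
}
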