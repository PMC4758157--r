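# Interaction networks, shared interaction ratio, ancestral interaction
# inference and the interaction-loss rate.
#
# Networks are undirected, with per-edge distinct-study counts and a source
# tag (experimental | structural). The multiple-confidence (MC) mode keeps
# experimental edges supported by at least two distinct studies; structural
# edges are merged in only where no experimental edge already exists.

#' Build an evidence-filtered interaction network
#'
#' @param records data.frame with columns `protein_a`, `protein_b`,
#'   `study_id` and optionally `source` (`"experimental"` default,
#'   or `"structural"`).
#' @param mode `"MC"` (multiple confidence: experimental edges need >= 2
#'   distinct studies; duplicated study ids count once) or `"all"` (every
#'   experimental edge kept). Structural edges are then added iff the edge
#'   is not already present.
#' @return An object of class `ppi_network`: list with `edges` (data.frame
#'   `a`, `b`, `n_studies`, `source`), `proteins`, `adj` (named list of
#'   partner sets) and `mode`. Self-interactions are permitted.
#' @export
build_network <- function(records, mode = c("MC", "all")) {
  mode <- match.arg(mode)
  needed <- c("protein_a", "protein_b", "study_id")
  if (!all(needed %in% names(records)))
    stop("evidence records need columns: ", paste(needed, collapse = ", "))
  records <- as.data.frame(records)
  bad <- which(is.na(records$protein_a) | is.na(records$protein_b) |
                 is.na(records$study_id) | records$study_id == "" |
                 records$protein_a == "" | records$protein_b == "")
  if (length(bad))
    stop("malformed evidence record at line ", bad[1])
  if (is.null(records$source))
    records$source <- rep("experimental", nrow(records))

  # canonical unordered edge key
  a <- pmin(records$protein_a, records$protein_b)
  b <- pmax(records$protein_a, records$protein_b)
  key <- paste(a, b, sep = "\r")

  exp <- records$source == "experimental"
  edges <- NULL
  if (any(exp)) {
    dedup <- !duplicated(paste(key, records$study_id)[exp])
    ek <- key[exp][dedup]
    tab <- table(ek)
    keep <- if (mode == "MC") names(tab)[tab >= 2] else names(tab)
    if (length(keep)) {
      parts <- strsplit(keep, "\r", fixed = TRUE)
      edges <- data.frame(a = vapply(parts, `[`, "", 1),
                          b = vapply(parts, `[`, "", 2),
                          n_studies = as.integer(tab[keep]),
                          source = "experimental", stringsAsFactors = FALSE)
    }
  }
  if (any(!exp)) {
    sk <- unique(key[!exp])
    sk <- setdiff(sk, if (is.null(edges)) character(0)
                  else paste(edges$a, edges$b, sep = "\r"))
    if (length(sk)) {
      parts <- strsplit(sk, "\r", fixed = TRUE)
      edges <- rbind(edges, data.frame(
        a = vapply(parts, `[`, "", 1), b = vapply(parts, `[`, "", 2),
        n_studies = 1L, source = "structural", stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(a = character(0), b = character(0),
                        n_studies = integer(0), source = character(0))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL

  proteins <- sort(unique(c(edges$a, edges$b)))
  adj <- lapply(stats::setNames(proteins, proteins), function(p) {
    sort(unique(c(edges$b[edges$a == p], edges$a[edges$b == p])))
  })
  structure(list(edges = edges, proteins = proteins, adj = adj, mode = mode),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network (", x$mode, " mode): ", length(x$proteins),
      " proteins, ", nrow(x$edges), " edges (",
      sum(x$edges$source == "structural"), " structural)\n", sep = "")
  invisible(x)
}

#' Partner set of a protein in a network
#'
#' Includes the protein itself when a self-interaction edge exists.
#'
#' @param network a `ppi_network`.
#' @param protein identifier.
#' @return Character vector of partners (empty if absent from the network).
#' @export
network_partners <- function(network, protein) {
  p <- network$adj[[protein]]
  if (is.null(p)) character(0) else p
}

#' Shared interaction ratio of a duplicate pair
#'
#' `SIR = 2 s / (n1 + n2)`, where s is the number of partners shared by the
#' two members and n1, n2 their partner counts. Defined only when both
#' members have at least one interaction; otherwise the pair is excluded
#' (an error unless `strict = FALSE`, which returns `NULL`). Shared-partner
#' matching is by partner identity: interactions with the paralogue itself
#' and self-interactions count as ordinary partners.
#'
#' @param gene_a,gene_b member identifiers.
#' @param network a `ppi_network`.
#' @param strict error on excluded pairs (default) or return `NULL`.
#' @return List with `gene_a`, `gene_b`, `s`, `n1`, `n2`, `sir`.
#' @export
compute_sir <- function(gene_a, gene_b, network, strict = TRUE) {
  p1 <- network_partners(network, gene_a)
  p2 <- network_partners(network, gene_b)
  if (!length(p1) || !length(p2)) {
    if (strict) stop("pair excluded: a member has no interactions (",
                     gene_a, ", ", gene_b, ")")
    return(NULL)
  }
  s <- length(intersect(p1, p2))
  list(gene_a = gene_a, gene_b = gene_b, s = s,
       n1 = length(p1), n2 = length(p2),
       sir = 2 * s / (length(p1) + length(p2)))
}

#' Infer ancestral interaction counts and observed losses for a pair
#'
#' Assumes both members held the union U of their current partner sets
#' immediately after duplication: the ancestral interaction count is
#' `a = 2 |U|` (gene-partner interactions, not partners) and the loss count
#' is one per member-partner interaction now absent,
#' `l = (|U| - |P_A|) + (|U| - |P_B|)`. Losses that occurred in both
#' members are invisible to this inference (the partner drops out of U),
#' which biases downstream rate estimates downward; see
#' [estimate_loss_rate()].
#'
#' @param gene_a,gene_b member identifiers.
#' @param network a `ppi_network`.
#' @param convention `"gene_partner"` (a = 2|U|, default) or `"partner"`
#'   (a = |U|, l = partners fully lost by at least one member -- same ratio
#'   semantics on partners instead of gene-partner interactions).
#' @return List with `a`, `l`, `union_size`; `NULL` if U is empty.
#' @export
infer_ancestral_interactions <- function(gene_a, gene_b, network,
                                         convention = c("gene_partner",
                                                        "partner")) {
  convention <- match.arg(convention)
  p1 <- network_partners(network, gene_a)
  p2 <- network_partners(network, gene_b)
  u <- union(p1, p2)
  if (!length(u)) return(NULL)
  if (convention == "gene_partner") {
    a <- 2L * length(u)
    l <- (length(u) - length(p1)) + (length(u) - length(p2))
  } else {
    a <- length(u)
    l <- length(u) - length(intersect(p1, p2))
  }
  list(a = a, l = l, union_size = length(u))
}

#' Interaction-loss rate per interaction per million years
#'
#' `rate = (l / a) / d`: the fraction of ancestral gene-partner
#' interactions lost, per Myr. For whole-genome duplicates the pipeline
#' uses d = 100 Myr.
#'
#' @param l lost-interaction count (0 <= l <= a).
#' @param a ancestral interaction count (> 0).
#' @param d Myr since duplication (> 0).
#' @return Numeric rate.
#' @export
estimate_loss_rate <- function(l, a, d = 100) {
  if (a <= 0) stop("ancestral interaction count must be > 0")
  if (d <= 0) stop("divergence time must be > 0")
  if (l < 0 || l > a) stop("l must satisfy 0 <= l <= a")
  (l / a) / d
}

#' Cohort interaction-loss rate
#'
#' Sums losses and ancestral interactions over a cohort of duplicate pairs
#' and applies [estimate_loss_rate()]. Two accounting routes:
#' `source = "network"` infers (l, a) per pair from observed partner sets
#' via [infer_ancestral_interactions()] (the route available on real data;
#' biased downward by double losses), while `source = "truth"` uses the
#' planted ancestral sets of [simulate_interaction_loss()] (unbiased;
#' available only on synthetic data).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (network route),
#'   or the `truth` element of [simulate_interaction_loss()] (truth route).
#' @param network a `ppi_network` (network route).
#' @param d Myr since duplication.
#' @param source `"network"` or `"truth"`.
#' @return List with `rate`, `l`, `a`, `d`, `n_pairs_used`.
#' @export
estimate_loss_rate_cohort <- function(pairs, network = NULL, d = 100,
                                      source = c("network", "truth")) {
  source <- match.arg(source)
  if (source == "truth") {
    a <- 2L * sum(vapply(pairs, function(t) length(t$ancestral), integer(1)))
    l <- sum(vapply(pairs, function(t)
      length(t$lost_a) + length(t$lost_b), integer(1)))
    used <- length(pairs)
  } else {
    a <- 0L; l <- 0L; used <- 0L
    for (i in seq_len(nrow(pairs))) {
      anc <- infer_ancestral_interactions(pairs$gene_a[i], pairs$gene_b[i],
                                          network)
      if (is.null(anc)) next
      a <- a + anc$a; l <- l + anc$l; used <- used + 1L
    }
    if (a == 0) stop("no pair with any observed interaction")
  }
  list(rate = estimate_loss_rate(l, a, d), l = l, a = a, d = d,
       n_pairs_used = used)
}

#' Hub proteins of a network
#'
#' @param network a `ppi_network`.
#' @param threshold degree cutoff; proteins with strictly more partners are
#'   hubs (default 40).
#' @return Character vector of hub protein ids.
#' @export
find_hubs <- function(network, threshold = 40) {
  deg <- lengths(network$adj)
  names(deg)[deg > threshold]
}

#' Correlate per-pair divergence with SIR
#'
#' Rank (Spearman) correlation with p-value, Pearson reported alongside.
#'
#' @param x per-pair divergence values (e.g. relative interface
#'   substitution rate).
#' @param y per-pair SIR values, same length.
#' @return List with `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `pearson_p`, `n`.
#' @export
correlate_divergence_with_sir <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  pe <- stats::cor.test(x, y, method = "pearson")
  list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       n = length(x))
}

#' Write a network as a TSV edge list plus a JSON summary
#'
#' @param network a `ppi_network`.
#' @param edge_path TSV output (a, b, n_studies, source).
#' @param summary_path optional JSON output (n_edges, n_structural, hubs).
#' @param hub_threshold degree cutoff for the hub list.
#' @export
write_network <- function(network, edge_path, summary_path = NULL,
                          hub_threshold = 40) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(mode = network$mode,
           n_proteins = length(network$proteins),
           n_edges = nrow(network$edges),
           n_structural = sum(network$edges$source == "structural"),
           hubs = find_hubs(network, hub_threshold)),
      summary_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(edge_path)
}
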