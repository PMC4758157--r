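# Synthetic-data generators with planted ground truth.
#
# Every input the pipeline consumes can be generated here: two-chain
# complexes with a planted contact interface, duplicate pairs with
# controlled substitution densities inside/outside the interface,
# interaction networks in which duplicate pairs lose ancestral interactions
# at a known per-interaction rate, and codon alignments evolved on a fixed
# tree with site classes of known omega. Each generator records
# machine-readable truth so downstream estimators can be tested against it.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive a sub-seed (< 2^31) from a base seed and an operation offset
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}

# fixed 8-taxon tree at yeast-like divergence (several synonymous
# substitutions per codon site summed over the tree)
.default_tree <- paste0(
  "((((t1:0.40,t2:0.40):0.30,(t3:0.35,t4:0.35):0.35):0.25,",
  "(t5:0.60,t6:0.60):0.30):0.20,(t7:0.75,t8:0.75):0.35);")

#' Scenario configuration for the synthetic generators
#'
#' Defaults describe the study conditions emulated throughout: a cohort of
#' whole-genome duplicates about 100 Myr old losing interactions at
#' 6.0e-3 per interaction per Myr, substitution density inside interfaces
#' about three quarters of the outside density, and codon alignments of
#' eight taxa with a constrained (omega = 0.1) and a neutral (omega = 1)
#' site class.
#'
#' @param seed integer RNG seed; identical configs give bit-identical
#'   outputs.
#' @param n_pairs number of duplicate pairs in a cohort (default 204).
#' @param chain_length residues per chain in toy complexes (default 60).
#' @param interface_size planted interface residues per chain (default 10).
#' @param p_sub_interface,p_sub_noninterface per-site substitution
#'   probabilities inside/outside the interface (defaults 0.15 / 0.20).
#' @param loss_rate interaction losses per interaction per Myr
#'   (default 6.0e-3).
#' @param divergence_time Myr since duplication (default 100, whole-genome
#'   duplication age).
#' @param ancestral_degree_mean mean ancestral partner count per pair
#'   (default 3); degrees are Poisson-distributed, truncated to >= 1.
#' @param tree Newick string for codon simulation (default: fixed 8-taxon
#'   tree).
#' @param site_classes data.frame with columns `label`, `omega`, `n_sites`
#'   partitioning the simulated alignment.
#' @param p_preserve probability that a planted interface substitution
#'   preserves its atom contact (default 0.5).
#' @param p_syn probability that an unsubstituted site carries a synonymous
#'   codon change (default 0.1).
#' @param p_gap per-site deletion probability in the paralogue (default 0).
#' @param coupling probability that a pair's interaction status is forced to
#'   agree with its contact-preservation truth (default 0.5: contact
#'   preservation is informative about, but does not determine, interaction
#'   fate; 1 = fully determined, 0 = independent).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_pairs = 204L,
                            chain_length = 60L,
                            interface_size = 10L,
                            p_sub_interface = 0.15,
                            p_sub_noninterface = 0.20,
                            loss_rate = 6.0e-3,
                            divergence_time = 100,
                            ancestral_degree_mean = 3,
                            tree = .default_tree,
                            site_classes = data.frame(
                              label = c("constrained", "neutral"),
                              omega = c(0.1, 1.0),
                              n_sites = c(60L, 140L)),
                            p_preserve = 0.5,
                            p_syn = 0.1,
                            p_gap = 0,
                            coupling = 0.5) {
  cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
              chain_length = as.integer(chain_length),
              interface_size = as.integer(interface_size),
              p_sub_interface = p_sub_interface,
              p_sub_noninterface = p_sub_noninterface,
              loss_rate = loss_rate, divergence_time = divergence_time,
              ancestral_degree_mean = ancestral_degree_mean,
              tree = tree, site_classes = site_classes,
              p_preserve = p_preserve, p_syn = p_syn, p_gap = p_gap,
              coupling = coupling)
  probs <- c(cfg$p_sub_interface, cfg$p_sub_noninterface, cfg$p_preserve,
             cfg$p_syn, cfg$p_gap, cfg$coupling)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$loss_rate < 0) stop("loss_rate must be >= 0")
  if (cfg$divergence_time <= 0) stop("divergence_time must be > 0")
  if (cfg$interface_size > cfg$chain_length)
    stop("interface_size must be <= chain_length")
  if (cfg$interface_size < 1) stop("interface_size must be >= 1")
  if (cfg$n_pairs < 1) stop("n_pairs must be >= 1")
  if (!all(c("label", "omega", "n_sites") %in% names(cfg$site_classes)))
    stop("site_classes needs columns label, omega, n_sites")
  if (any(cfg$site_classes$omega < 0)) stop("omega must be >= 0")
  class(cfg) <- "scenario_config"
  cfg
}

# geometry constants for toy complexes
.toy <- list(spacing = 4.5,    # x distance between consecutive residues (A)
             sep = 16,         # y distance between the two chain baselines
             contact_slack = 0.2) # planted contact distance = r1+r2+slack

# atoms of one residue laid out at center (x0, y0); side chain stacks in z.
# If protrude_to is non-NULL the distal side-chain atom is placed there.
.residue_atoms <- function(chain_id, index, type, x0, y0,
                           protrude_to = NULL) {
  names <- c(.backbone_atoms, .side_chain_atoms[[type]])
  off <- rbind(N = c(-1.2, 0.4, 0), CA = c(0, 0, 0),
               C = c(1.2, 0.4, 0), O = c(1.9, 0.0, 0.9))
  sc <- .side_chain_atoms[[type]]
  pos <- matrix(NA_real_, nrow = length(names), ncol = 3)
  pos[1:4, ] <- sweep(off, 2, c(x0, y0, 0), "+")
  if (length(sc)) {
    for (k in seq_along(sc))
      pos[4 + k, ] <- c(x0 + 0.3, y0, 1.2 + 0.8 * (k - 1))
    if (!is.null(protrude_to))
      pos[4 + length(sc), ] <- protrude_to
  }
  data.frame(chain_id = chain_id, residue_index = index,
             residue_type = type, atom_name = names,
             element = element_from_atom_name(names),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

# distal side-chain atom name and radius for a residue type
.distal_atom <- function(type, radii = vdw_radii_bondi()) {
  sc <- .side_chain_atoms[[type]]
  if (!length(sc)) return(NULL)
  name <- sc[length(sc)]
  list(name = name, radius = unname(radii[element_from_atom_name(name)]))
}

#' Generate a two-chain toy complex with a planted interface
#'
#' Chains A and B run parallel, 16 A apart, with residues every 4.5 A. At
#' `interface_size` randomly chosen residue positions, the distal side-chain
#' atoms of the facing residues protrude toward the midline and meet at a
#' distance 0.2 A above the sum of their van der Waals radii -- inside the
#' 0.5 A contact margin but clash-free. Every other inter-chain atom pair
#' clears the contact threshold by more than 1 A, so contact detection
#' recovers exactly the planted residues.
#'
#' @param config a [scenario_config()].
#' @return List with `structure` (a [complex_structure()]), `interface`
#'   (planted truth: `residues_a`, `residues_b`, sorted indices) and
#'   `interface_positions` (the shared residue indices).
#' @export
gen_toy_complex <- function(config) {
  L <- config$chain_length
  with_seed(derive_seed(config$seed, 1L), {
    pos <- sort(sample.int(L, config$interface_size))
    seq_a <- sample(.aa3, L, replace = TRUE)
    seq_b <- sample(.aa3, L, replace = TRUE)
    non_gly <- setdiff(.aa3, "GLY")
    seq_a[pos] <- sample(non_gly, length(pos), replace = TRUE)
    seq_b[pos] <- sample(non_gly, length(pos), replace = TRUE)

    mid <- .toy$sep / 2
    rows <- vector("list", 2 * L)
    for (i in seq_len(L)) {
      x0 <- i * .toy$spacing
      prot_a <- prot_b <- NULL
      if (i %in% pos) {
        ra <- .distal_atom(seq_a[i])$radius
        rb <- .distal_atom(seq_b[i])$radius
        d <- ra + rb + .toy$contact_slack
        prot_a <- c(x0, mid - d / 2, 0)
        prot_b <- c(x0, mid + d / 2, 0)
      }
      rows[[2 * i - 1]] <- .residue_atoms("A", i, seq_a[i], x0, 0, prot_a)
      rows[[2 * i]] <- .residue_atoms("B", i, seq_b[i], x0, .toy$sep, prot_b)
    }
    st <- complex_structure(do.call(rbind, rows))
    list(structure = st,
         interface = list(residues_a = pos, residues_b = pos),
         interface_positions = pos)
  })
}

#' Generate a duplicate pair: a paralogue model of chain A with planted
#' substitutions
#'
#' Chain A of the complex is treated as one member of a duplicate gene pair;
#' the generated paralogue substitutes each site with probability
#' `p_sub_interface` (interface sites) or `p_sub_noninterface` (elsewhere).
#' A substituted residue's side chain is rebuilt with the new residue type's
#' canonical atoms; at interface sites a planted flag decides whether the
#' rebuilt side chain keeps the protruding contact atom (contact preserved)
#' or is withdrawn to the chain baseline (contact broken). Deletions
#' (probability `p_gap`) appear as gaps in the paralogue sequence; in the
#' model the residue is reduced to its backbone. Codon sequences consistent
#' with both protein sequences are emitted, with synonymous changes at
#' unsubstituted sites at rate `p_syn`.
#'
#' @param complex,interface output of [gen_toy_complex()].
#' @param config a [scenario_config()].
#' @param pair_index integer; distinguishes pairs generated under one
#'   config.
#' @return An object of class `duplicate_pair`; its `truth` field is a
#'   per-site table (site, region, substituted, gap, from, to,
#'   contact_preserved).
#' @export
gen_duplicate_pair <- function(complex, interface, config, pair_index = 1L) {
  st <- complex$structure
  L <- config$chain_length
  ipos <- interface$residues_a
  with_seed(derive_seed(config$seed, 100L + pair_index), {
    seq_a <- strsplit(chain_sequences(st)[["A"]], "")[[1]]
    type_a <- aa1_to_3(seq_a)

    region <- ifelse(seq_len(L) %in% ipos, "interface", "non_interface")
    p_sub <- ifelse(region == "interface",
                    config$p_sub_interface, config$p_sub_noninterface)
    substituted <- stats::runif(L) < p_sub
    gap <- !substituted & stats::runif(L) < config$p_gap

    new_type <- type_a
    preserved <- rep(NA, L)
    non_gly <- setdiff(.aa3, "GLY")
    for (i in which(substituted)) {
      choices <- setdiff(if (region[i] == "interface") non_gly else .aa3,
                         type_a[i])
      new_type[i] <- sample(choices, 1)
      if (region[i] == "interface")
        preserved[i] <- stats::runif(1) < config$p_preserve
    }

    # rebuild the model structure
    atoms <- st$atoms
    keep_b <- atoms[atoms$chain_id == "B", , drop = FALSE]
    rows <- vector("list", L)
    mid <- .toy$sep / 2
    for (i in seq_len(L)) {
      x0 <- i * .toy$spacing
      if (gap[i]) {
        r <- .residue_atoms("A", i, type_a[i], x0, 0)
        rows[[i]] <- r[r$atom_name %in% .backbone_atoms, ]
      } else if (substituted[i]) {
        prot <- NULL
        if (i %in% ipos && isTRUE(preserved[i])) {
          # keep the template's protrusion point: the contact survives any
          # residue swap because heavy-atom radii differ by < 0.3 A while
          # the contact margin is 0.5 A
          tmpl <- atoms[atoms$chain_id == "A" & atoms$residue_index == i, ]
          prot <- as.numeric(tmpl[which.max(tmpl$y), c("x", "y", "z")])
        }
        rows[[i]] <- .residue_atoms("A", i, new_type[i], x0, 0, prot)
      } else {
        rows[[i]] <- atoms[atoms$chain_id == "A" &
                             atoms$residue_index == i, names(atoms)[1:8]]
      }
    }
    model_atoms <- rbind(do.call(rbind, rows)[, 1:8], keep_b[, 1:8])
    model <- complex_structure(model_atoms)

    seq_b_aligned <- aa3_to_1(new_type)
    seq_b_aligned[gap] <- "-"

    # codon sequences consistent with the two protein sequences
    gc <- .genetic_code()
    syn_codons <- function(aa) names(gc)[gc == aa]
    cod_a <- vapply(seq_a, function(a) {
      cs <- syn_codons(a); cs[sample.int(length(cs), 1)]
    }, character(1))
    cod_b <- cod_a
    for (i in seq_len(L)) {
      if (gap[i]) {
        cod_b[i] <- "---"
      } else if (substituted[i]) {
        cs <- syn_codons(aa3_to_1(new_type[i]))
        cod_b[i] <- cs[sample.int(length(cs), 1)]
      } else if (stats::runif(1) < config$p_syn) {
        cs <- setdiff(syn_codons(seq_a[i]), cod_a[i])
        if (length(cs)) cod_b[i] <- cs[sample.int(length(cs), 1)]
      }
    }

    truth <- data.frame(site = seq_len(L), region = region,
                        substituted = substituted, gap = gap,
                        from = seq_a, to = seq_b_aligned,
                        contact_preserved = preserved,
                        stringsAsFactors = FALSE)
    structure(list(gene_a = sprintf("G%da", pair_index),
                   gene_b = sprintf("G%db", pair_index),
                   duplication_class = "WGD",
                   age = config$divergence_time,
                   aligned_seq_a = paste(seq_a, collapse = ""),
                   aligned_seq_b = paste(seq_b_aligned, collapse = ""),
                   codon_seq_a = paste(cod_a, collapse = ""),
                   codon_seq_b = paste(cod_b, collapse = ""),
                   interface_sites = ipos,
                   template = st, model = model, truth = truth),
              class = "duplicate_pair")
  })
}

#' @export
print.duplicate_pair <- function(x, ...) {
  cat("duplicate_pair ", x$gene_a, "/", x$gene_b, " (",
    x$duplication_class, ", ", x$age, " Myr): ",
    sum(x$truth$substituted), " substitutions (",
    sum(x$truth$substituted & x$truth$region == "interface"),
    " in interface), ", sum(x$truth$gap), " gaps\n", sep = "")
  invisible(x)
}

#' Simulate interaction loss after duplication
#'
#' Each duplicate pair starts with both members holding an identical
#' ancestral partner set (Poisson-sized around `ancestral_degree_mean`,
#' truncated to >= 1); every (gene, partner) interaction is then lost
#' independently with probability `loss_rate * divergence_time`. Surviving
#' interactions are emitted as evidence records carrying two distinct
#' synthetic study ids each, so the multiple-confidence filter retains
#' them.
#'
#' @param config a [scenario_config()].
#' @param forced_status optional character vector (length `n_pairs`) of
#'   `NA`, `"conserved"` or `"diverged"`; non-NA entries override the
#'   random outcome so the pair's partner sets are identical / differ.
#' @return List with `records` (data.frame protein_a, protein_b, study_id,
#'   source) and `truth`: per-pair list of `ancestral` partners, `lost_a`,
#'   `lost_b`, plus the total ancestral interaction count `a_total` (2 per
#'   pair-partner), total losses `l_total`, and the per-interaction loss
#'   probability used.
#' @export
simulate_interaction_loss <- function(config, forced_status = NULL) {
  p <- config$loss_rate * config$divergence_time
  if (p > 1) stop("loss probability loss_rate * divergence_time exceeds 1")
  n <- config$n_pairs
  if (!is.null(forced_status)) stopifnot(length(forced_status) == n)
  with_seed(derive_seed(config$seed, 2L), {
    recs <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      k <- max(1L, stats::rpois(1, config$ancestral_degree_mean))
      partners <- sprintf("P%d_%d", i, seq_len(k))
      lost_a <- stats::runif(k) < p
      lost_b <- stats::runif(k) < p
      if (!is.null(forced_status) && !is.na(forced_status[i])) {
        if (forced_status[i] == "conserved") {
          lost_a[] <- FALSE; lost_b[] <- FALSE
        } else if (identical(lost_a, lost_b)) {
          lost_b[1] <- !lost_a[1]
        }
      }
      ga <- sprintf("G%da", i); gb <- sprintf("G%db", i)
      keep_a <- partners[!lost_a]; keep_b <- partners[!lost_b]
      edges <- rbind(
        if (length(keep_a)) data.frame(protein_a = ga, protein_b = keep_a),
        if (length(keep_b)) data.frame(protein_a = gb, protein_b = keep_b))
      if (!is.null(edges) && nrow(edges)) {
        recs[[i]] <- data.frame(
          protein_a = rep(edges$protein_a, each = 2),
          protein_b = rep(edges$protein_b, each = 2),
          study_id = rep(c("S1", "S2"), nrow(edges)),
          source = "experimental", stringsAsFactors = FALSE)
      }
      truth[[i]] <- list(pair = i, gene_a = ga, gene_b = gb,
                         ancestral = partners,
                         lost_a = partners[lost_a], lost_b = partners[lost_b])
    }
    records <- do.call(rbind, Filter(Negate(is.null), recs))
    if (is.null(records))
      records <- data.frame(protein_a = character(0),
                            protein_b = character(0),
                            study_id = character(0), source = character(0))
    a_total <- 2L * sum(vapply(truth, function(t) length(t$ancestral),
                               integer(1)))
    l_total <- sum(vapply(truth, function(t)
      length(t$lost_a) + length(t$lost_b), integer(1)))
    list(records = records, truth = truth,
         a_total = a_total, l_total = l_total, loss_prob = p)
  })
}

#' Simulate a codon alignment on a tree with known per-site selection
#' classes
#'
#' Codons evolve down the tree by an omega-thinned mutation process: point
#' mutations arrive as a Poisson process (rate 1 per nucleotide site per
#' unit branch length), synonymous changes are always accepted,
#' nonsynonymous changes are accepted with the probability omega of the
#' site's class, and mutations creating stop codons are rejected. No
#' indels.
#'
#' @param config a [scenario_config()]; `tree` and `site_classes` define
#'   the simulation.
#' @return List with `alignment` (named character vector, one concatenated
#'   codon string per taxon), `tree` (an ape `phylo`), and `site_truth`
#'   (data.frame site, label, omega).
#' @export
gen_codon_alignment <- function(config) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = config$tree)),
                 error = function(e) NULL)
  if (is.null(tr)) stop("invalid Newick tree")
  sc <- config$site_classes
  n_sites <- sum(sc$n_sites)
  omega_site <- rep(sc$omega, sc$n_sites)
  label_site <- rep(as.character(sc$label), sc$n_sites)

  with_seed(derive_seed(config$seed, 3L), {
    sense <- sense_codons()
    root <- sample(sense, n_sites, replace = TRUE)
    n_nodes <- ape::Ntip(tr) + tr$Nnode
    seqs <- vector("list", n_nodes)
    root_node <- ape::Ntip(tr) + 1L
    seqs[[root_node]] <- root
    # preorder edge traversal so parents are assigned before children
    edges <- ape::reorder.phylo(tr, "cladewise")$edge
    bl <- tr$edge.length[match(paste(edges[, 1], edges[, 2]),
                               paste(tr$edge[, 1], tr$edge[, 2]))]
    if (is.null(tr$edge.length)) bl <- rep(0, nrow(edges))
    nts <- c("A", "C", "G", "T")
    gc <- .genetic_code()
    for (e in seq_len(nrow(edges))) {
      parent <- seqs[[edges[e, 1]]]
      child <- parent
      n_events <- stats::rpois(n_sites, 3 * bl[e])
      for (s in which(n_events > 0)) {
        for (ev in seq_len(n_events[s])) {
          pos <- sample.int(3, 1)
          cur <- child[s]
          alt <- cur
          substr(alt, pos, pos) <- sample(setdiff(nts, substr(cur, pos, pos)), 1)
          if (gc[[alt]] == "*") next
          if (gc[[alt]] == gc[[cur]] || stats::runif(1) < omega_site[s])
            child[s] <- alt
        }
      }
      seqs[[edges[e, 2]]] <- child
    }
    aln <- vapply(seq_len(ape::Ntip(tr)),
                  function(i) paste(seqs[[i]], collapse = ""), character(1))
    names(aln) <- tr$tip.label
    list(alignment = aln, tree = tr,
         site_truth = data.frame(site = seq_len(n_sites),
                                 label = label_site, omega = omega_site))
  })
}

#' Write evidence records as a TSV table
#' @param records data.frame (protein_a, protein_b, study_id[, source]).
#' @param path output file.
#' @export
write_evidence_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
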