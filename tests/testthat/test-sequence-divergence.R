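# Alignment mapping, region counting, relative rate + filter, Ka/Ks,
# 2x2 classification, substitution matrices.

test_that("interface columns map through gaps correctly", {
  cols <- map_interface_to_alignment("ACDEFGHIKL", "ACDEFGHIKL", c(3, 5))
  expect_identical(which(cols == "interface"), c(3L, 5L))

  # a gap before residue 3 of member A shifts its interface columns right
  cols <- map_interface_to_alignment("AC-DEFGHIKL", "ACWDEFGHIKL", c(3, 5))
  expect_identical(which(cols == "interface"), c(4L, 6L))

  # either member's interface residues mark the column
  cols <- map_interface_to_alignment("ACDEF", "ACDEF", integer(0), 2)
  expect_identical(which(cols == "interface"), 2L)

  expect_identical(unique(map_interface_to_alignment("ACD", "ACD",
                                                     integer(0))),
                   "non_interface")
  expect_error(map_interface_to_alignment("ACD", "ACD", 9),
               "beyond sequence length")
})

test_that("substitution and gap counting conserves columns", {
  a <- "ACDEFGHIKL"
  b <- "ACDWF-HIKM"
  cols <- map_interface_to_alignment(a, b, c(4, 6))
  cnt <- count_substitutions(a, b, cols)
  expect_equal(sum(cnt$n_sites), nchar(a))
  i <- cnt[cnt$region == "interface", ]
  n <- cnt[cnt$region == "non_interface", ]
  expect_equal(i$n_subs, 1)   # column 4 W
  expect_equal(i$n_gaps, 1)   # column 6 gap, not a substitution
  expect_equal(n$n_subs, 1)   # column 10 M
  expect_true(all(cnt$n_subs + cnt$n_gaps <= cnt$n_sites))
  expect_error(count_substitutions("AC", "A", rep("interface", 2)),
               "length")
})

test_that("identical sequences give zero substitutions in both regions", {
  a <- "ACDEFGHIKL"
  cnt <- count_substitutions(a, a, map_interface_to_alignment(a, a, 1:3))
  expect_equal(sum(cnt$n_subs), 0)
  expect_equal(sum(cnt$n_gaps), 0)
})

test_that("relative rate recovers planted densities and applies the filter", {
  cfg <- scenario_config(seed = 60, chain_length = 1500,
                         interface_size = 500,
                         p_sub_interface = 0.1, p_sub_noninterface = 0.2)
  cx <- gen_toy_complex(cfg)
  dp <- gen_duplicate_pair(cx, cx$interface, cfg)
  cols <- map_interface_to_alignment(dp$aligned_seq_a, dp$aligned_seq_b,
                                     dp$interface_sites)
  cnt <- count_substitutions(dp$aligned_seq_a, dp$aligned_seq_b, cols)
  rate <- relative_interface_rate(cnt)
  expect_equal(rate$ratio, 0.5, tolerance = 0.1)
  expect_false(rate$excluded)

  # conserved interface, diverged elsewhere -> ratio 0
  counts0 <- data.frame(region = c("interface", "non_interface"),
                        n_sites = c(10, 90), n_subs = c(0, 30),
                        n_gaps = c(0, 0))
  expect_equal(relative_interface_rate(counts0)$ratio, 0)

  # ratio above the cap flags exclusion
  counts_hot <- data.frame(region = c("interface", "non_interface"),
                           n_sites = c(10, 90), n_subs = c(5, 18),
                           n_gaps = c(0, 0))
  r <- relative_interface_rate(counts_hot)
  expect_equal(r$ratio, 2.5)
  expect_true(r$excluded)

  # undefined when the non-interface rate is zero
  counts_und <- data.frame(region = c("interface", "non_interface"),
                           n_sites = c(10, 90), n_subs = c(2, 0),
                           n_gaps = c(0, 0))
  expect_true(is.na(relative_interface_rate(counts_und)$ratio))
})

test_that("pairwise divergence and Nei-Gojobori Ka/Ks behave on basics", {
  d <- pairwise_divergence("ACDEF", "ACDEF",
                           "GCCTGTGATGAATTT", "GCCTGTGATGAATTT")
  expect_equal(d$protein_divergence, 0)
  expect_equal(d$ka, 0)
  expect_equal(d$ks, 0)

  # one synonymous change over a single codon: Ks > 0, Ka = 0
  d <- pairwise_divergence("F", "F", "TTT", "TTC")
  expect_equal(d$ka, 0)
  expect_gt(d$ks, 0)
  expect_error(pairwise_divergence("FF", "FF", "TTTT", "TTTT"),
               "multiple of 3")
})

test_that("pathway counting matches exhaustive enumeration on random codons", {
  set.seed(9)
  sense <- sense_codons()
  for (k in 1:100) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    got <- ppidup:::ng_pathway_counts(a, b)
    want <- oracle_pathway_counts(a, b)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 label = paste(a, b))
  }
})

test_that("TTT site counts are 1/3 synonymous, 8/3 nonsynonymous", {
  s <- ng_site_counts("TTT")
  expect_equal(unname(s["syn"]), 1 / 3)
  expect_equal(unname(s["nonsyn"]), 8 / 3)
})

test_that("pair classification fills the 2x2 contingency consistently", {
  net <- build_network(records_for_partners("A", c("P1", "P2"),
                                            "B", c("P1", "P2")))
  cols <- rep(c("interface", "non_interface"), c(2, 3))

  cl <- classify_pair_divergence("p1", "ACDEF", "ACDEF", cols, "A", "B", net)
  expect_equal(cl$interface_status, "conserved")
  expect_equal(cl$interaction_status, "conserved")

  cl <- classify_pair_divergence("p2", "ACDEF", "WCDEF", cols, "A", "B", net)
  expect_equal(cl$interface_status, "diverged")
  expect_equal(cl$interaction_status, "conserved")

  # interface gap counts as divergence by default, not when disabled
  cl <- classify_pair_divergence("p3", "ACDEF", "-CDEF", cols, "A", "B", net)
  expect_equal(cl$interface_status, "diverged")
  cl <- classify_pair_divergence("p3", "ACDEF", "-CDEF", cols, "A", "B",
                                 net, gaps_diverge = FALSE)
  expect_equal(cl$interface_status, "conserved")

  netd <- build_network(records_for_partners("A", c("P1", "P2"), "B", "P1"))
  cl <- classify_pair_divergence("p4", "ACDEF", "ACDEF", cols, "A", "B", netd)
  expect_equal(cl$interaction_status, "diverged")

  # member absent from the network -> excluded (NULL), and table totals
  # count only classified pairs
  expect_null(classify_pair_divergence("p5", "ACDEF", "ACDEF", cols,
                                       "A", "Z", net))
  calls <- list(
    classify_pair_divergence("p1", "ACDEF", "ACDEF", cols, "A", "B", net),
    classify_pair_divergence("p2", "ACDEF", "WCDEF", cols, "A", "B", net),
    NULL)
  tab <- divergence_table(calls)
  expect_equal(sum(tab), 2)
})

test_that("substitution matrices are symmetric and conserve counts", {
  net <- build_network(records_for_partners("A", "P1", "B", "P1"))
  cols5 <- rep(c("interface", "non_interface"), c(4, 1))
  call <- classify_pair_divergence("p1", "MAC-F", "AACWF", cols5, "A", "B",
                                   net)
  m <- build_substitution_matrix(list(list(
    aligned_a = "MAC-F", aligned_b = "AACWF", columns = cols5,
    call = call)))
  expect_identical(m$conserved, t(m$conserved))
  expect_identical(m$diverged, t(m$diverged))
  expect_equal(m$conserved["M", "A"], 1)       # status is conserved
  expect_equal(m$conserved["-", "W"], 1)       # gap as the 21st symbol
  expect_equal(substitution_matrix_total(m), 2)
  # per-cell proportions over the two statuses sum to one
  tot <- m$conserved + m$diverged
  pr <- m$proportions
  expect_true(all(abs(pr[tot > 0] + (1 - pr[tot > 0]) - 1) < 1e-12))
  expect_error(build_substitution_matrix(list(list(
    aligned_a = "X", aligned_b = "A", columns = "interface", call = call))),
    "non-standard residue")
})

test_that("matrix totals equal interface substitutions plus gaps", {
  cfg <- scenario_config(seed = 71, n_pairs = 12, chain_length = 40,
                         interface_size = 8, p_sub_interface = 0.4,
                         p_gap = 0.05)
  sim <- simulate_interaction_loss(cfg)
  net <- build_network(sim$records, "MC")
  pair_data <- list()
  total_expected <- 0
  for (i in seq_len(cfg$n_pairs)) {
    cfg_i <- cfg; cfg_i$seed <- i
    cx <- gen_toy_complex(cfg_i)
    dp <- gen_duplicate_pair(cx, cx$interface, cfg_i, i)
    cols <- map_interface_to_alignment(dp$aligned_seq_a, dp$aligned_seq_b,
                                       dp$interface_sites)
    call <- classify_pair_divergence(i, dp$aligned_seq_a, dp$aligned_seq_b,
                                     cols, dp$gene_a, dp$gene_b, net)
    if (is.null(call)) next
    cnt <- count_substitutions(dp$aligned_seq_a, dp$aligned_seq_b, cols)
    total_expected <- total_expected +
      cnt$n_subs[cnt$region == "interface"] +
      cnt$n_gaps[cnt$region == "interface"]
    pair_data[[length(pair_data) + 1]] <-
      list(aligned_a = dp$aligned_seq_a, aligned_b = dp$aligned_seq_b,
           columns = cols, call = call)
  }
  m <- build_substitution_matrix(pair_data)
  expect_equal(substitution_matrix_total(m), total_expected)
  # order invariance of the marginal totals
  m2 <- build_substitution_matrix(rev(pair_data))
  expect_identical(m$conserved + m$diverged, m2$conserved + m2$diverged)
})
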