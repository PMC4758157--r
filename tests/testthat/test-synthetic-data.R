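# Generators: determinism, planted truth, loss process, codon simulation.

test_that("scenario_config enforces its invariants", {
  expect_error(scenario_config(p_sub_interface = 1.2), "probabilities")
  expect_error(scenario_config(loss_rate = -1), "loss_rate")
  expect_error(scenario_config(divergence_time = 0), "divergence_time")
  expect_error(scenario_config(interface_size = 100, chain_length = 50),
               "interface_size")
  expect_error(scenario_config(interface_size = 0), "interface_size")
})

test_that("identical configs give bit-identical PDB output", {
  cfg <- scenario_config(seed = 42, chain_length = 35, interface_size = 5)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(gen_toy_complex(cfg)$structure, f1)
  write_complex_pdb(gen_toy_complex(cfg)$structure, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the structure
  f3 <- withr::local_tempfile(fileext = ".pdb")
  cfg2 <- scenario_config(seed = 43, chain_length = 35, interface_size = 5)
  write_complex_pdb(gen_toy_complex(cfg2)$structure, f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("planted interfaces are exactly what contact detection finds", {
  for (seed in 1:5) {
    cfg <- scenario_config(seed = seed, chain_length = 45,
                           interface_size = 6)
    cx <- gen_toy_complex(cfg)
    iface <- identify_interface(
      detect_atom_contacts(cx$structure, "A", "B"))
    expect_identical(iface$residues_a, cx$interface$residues_a)
    expect_identical(iface$residues_b, cx$interface$residues_b)
    # non-contact pairs clear the threshold by at least 1 A
    wide <- detect_atom_contacts(cx$structure, "A", "B", margin = 1.5)
    expect_identical(contact_keys(wide),
                     contact_keys(iface$contacts))
  }
})

test_that("zero substitution probabilities give an identical paralogue", {
  cfg <- scenario_config(seed = 8, chain_length = 30, interface_size = 4,
                         p_sub_interface = 0, p_sub_noninterface = 0,
                         p_syn = 0)
  cx <- gen_toy_complex(cfg)
  dp <- gen_duplicate_pair(cx, cx$interface, cfg)
  expect_identical(dp$aligned_seq_a, dp$aligned_seq_b)
  expect_identical(dp$codon_seq_a, dp$codon_seq_b)
  expect_equal(sum(dp$truth$substituted), 0)
})

test_that("generator truth matches downstream substitution counts", {
  cfg <- scenario_config(seed = 12, chain_length = 80, interface_size = 15,
                         p_sub_interface = 0.4, p_sub_noninterface = 0.3)
  cx <- gen_toy_complex(cfg)
  dp <- gen_duplicate_pair(cx, cx$interface, cfg)
  cols <- map_interface_to_alignment(dp$aligned_seq_a, dp$aligned_seq_b,
                                     dp$interface_sites)
  cnt <- count_substitutions(dp$aligned_seq_a, dp$aligned_seq_b, cols)
  tr <- dp$truth
  expect_equal(cnt$n_subs[cnt$region == "interface"],
               sum(tr$substituted & tr$region == "interface"))
  expect_equal(cnt$n_subs[cnt$region == "non_interface"],
               sum(tr$substituted & tr$region == "non_interface"))
})

test_that("codon sequences translate to the planted protein sequences", {
  cfg <- scenario_config(seed = 13, chain_length = 40, interface_size = 6,
                         p_sub_interface = 0.5, p_sub_noninterface = 0.3)
  cx <- gen_toy_complex(cfg)
  dp <- gen_duplicate_pair(cx, cx$interface, cfg)
  cods <- substring(dp$codon_seq_a, seq(1, nchar(dp$codon_seq_a), 3),
                    seq(3, nchar(dp$codon_seq_a), 3))
  expect_identical(paste(translate_codons(cods), collapse = ""),
                   dp$aligned_seq_a)
})

test_that("the loss process hits its expected fraction within 3 sigma", {
  cfg <- scenario_config(seed = 77, n_pairs = 2000, loss_rate = 6e-3,
                         divergence_time = 100, ancestral_degree_mean = 3)
  sim <- simulate_interaction_loss(cfg)
  expect_gt(sim$a_total, 1e4)
  p <- sim$loss_prob
  se <- sqrt(p * (1 - p) / sim$a_total)
  expect_lt(abs(sim$l_total / sim$a_total - p), 3 * se)
})

test_that("zero loss rate keeps every ancestral interaction (SIR = 1)", {
  cfg <- scenario_config(seed = 5, n_pairs = 30, loss_rate = 0)
  sim <- simulate_interaction_loss(cfg)
  expect_equal(sim$l_total, 0)
  net <- build_network(sim$records, mode = "MC")
  for (t in sim$truth) {
    s <- compute_sir(t$gene_a, t$gene_b, net)
    expect_equal(s$sir, 1)
  }
})

test_that("an impossible loss probability is rejected", {
  cfg <- scenario_config(seed = 1, loss_rate = 0.02, divergence_time = 100)
  expect_error(simulate_interaction_loss(cfg), "exceeds 1")
})

test_that("omega = 0 sites admit no amino-acid change across the tree", {
  cfg <- scenario_config(seed = 3, site_classes = data.frame(
    label = "invariant", omega = 0, n_sites = 40L))
  aln <- gen_codon_alignment(cfg)
  mat <- vapply(aln$alignment, function(s)
    translate_codons(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))),
    character(40))
  expect_true(all(apply(mat, 1, function(r) length(unique(r)) == 1)))
})

test_that("zero branch lengths leave all taxa identical to the root", {
  tree0 <- "((t1:0,t2:0):0,(t3:0,t4:0):0);"
  cfg <- scenario_config(seed = 3, tree = tree0, site_classes = data.frame(
    label = "neutral", omega = 1, n_sites = 20L))
  aln <- gen_codon_alignment(cfg)
  expect_length(unique(unname(aln$alignment)), 1)
})

test_that("neutral sites accumulate N and S in the expected-site ratio", {
  cfg <- scenario_config(seed = 19, site_classes = data.frame(
    label = "neutral", omega = 1, n_sites = 400L))
  aln <- gen_codon_alignment(cfg)
  scan <- site_selection_scan(aln$tree, aln$alignment)
  # aggregate observed nonsynonymous share vs expected share
  obs <- sum(scan$N_obs) / sum(scan$N_obs + scan$S_obs)
  exp_share <- sum(scan$EN) / sum(scan$EN + scan$ES)
  expect_equal(obs, exp_share, tolerance = 0.05)
})

test_that("an invalid tree is rejected", {
  cfg <- scenario_config(seed = 1)
  cfg$tree <- "not a tree (("
  expect_error(gen_codon_alignment(cfg), "invalid Newick")
})

test_that("generators are deterministic across repeated calls", {
  cfg <- scenario_config(seed = 50, n_pairs = 10, chain_length = 30,
                         interface_size = 4)
  expect_identical(simulate_interaction_loss(cfg),
                   simulate_interaction_loss(cfg))
  expect_identical(gen_codon_alignment(cfg), gen_codon_alignment(cfg))
  cx <- gen_toy_complex(cfg)
  expect_identical(gen_duplicate_pair(cx, cx$interface, cfg, 3),
                   gen_duplicate_pair(cx, cx$interface, cfg, 3))
})
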