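# Contact criterion, interface derivation, burial and atom roles, SASA.

test_that("contact threshold arithmetic follows the vdW + margin rule", {
  # two carbons: threshold 1.70 + 1.70 + 0.5 = 3.90
  expect_equal(nrow(detect_atom_contacts(two_atom_structure(3.85), "A", "B")), 1)
  expect_equal(nrow(detect_atom_contacts(two_atom_structure(3.95), "A", "B")), 0)
  ct <- detect_atom_contacts(two_atom_structure(2.90), "A", "B")
  expect_equal(nrow(ct), 1)
  expect_true(ct$clash)  # 2.90 < 3.40 = sum of radii
  # non-clash contact
  expect_false(detect_atom_contacts(two_atom_structure(3.85), "A", "B")$clash)
})

test_that("cell-list search equals the brute-force oracle and is symmetric", {
  for (seed in 1:5) {
    cfg <- scenario_config(seed = seed, chain_length = 40, interface_size = 7)
    st <- gen_toy_complex(cfg)$structure
    cell <- detect_atom_contacts(st, "A", "B", method = "cell")
    brute <- detect_atom_contacts(st, "A", "B", method = "brute")
    expect_identical(contact_keys(cell), contact_keys(brute))
    expect_identical(contact_keys(cell), brute_contact_pairs(st, "A", "B"))
    # symmetry: (B, A) gives the same pairs with roles swapped
    rev <- detect_atom_contacts(st, "B", "A")
    expect_identical(contact_keys(cell),
                     sort(paste(rev$residue_b, rev$atom_b,
                                rev$residue_a, rev$atom_a)))
  }
})

test_that("contact sets grow monotonically with the margin", {
  st <- gen_toy_complex(scenario_config(seed = 11, chain_length = 40,
                                        interface_size = 8))$structure
  k1 <- contact_keys(detect_atom_contacts(st, "A", "B", margin = 0.2))
  k2 <- contact_keys(detect_atom_contacts(st, "A", "B", margin = 0.5))
  k3 <- contact_keys(detect_atom_contacts(st, "A", "B", margin = 2.0))
  expect_true(all(k1 %in% k2))
  expect_true(all(k2 %in% k3))
})

test_that("identify_interface collects exactly the contacting residues", {
  empty <- detect_atom_contacts(two_atom_structure(10), "A", "B")
  iface <- identify_interface(empty)
  expect_length(iface$residues_a, 0)
  expect_length(iface$residues_b, 0)

  one <- data.frame(chain_a = "A", residue_a = 12L, atom_a = "CB",
                    chain_b = "B", residue_b = 77L, atom_b = "CD1",
                    distance = 3.5, clash = FALSE)
  iface <- identify_interface(one)
  expect_equal(iface$residues_a, 12L)
  expect_equal(iface$residues_b, 77L)

  mixed <- rbind(one, data.frame(chain_a = "A", residue_a = 1L,
                                 atom_a = "CB", chain_b = "C",
                                 residue_b = 2L, atom_b = "CB",
                                 distance = 3, clash = FALSE))
  expect_error(identify_interface(mixed), "multiple chain pairs")
})

test_that("clash contacts contribute interface residues like ordinary ones", {
  st <- two_atom_structure(2.9)  # clash
  iface <- identify_interface(detect_atom_contacts(st, "A", "B"))
  expect_equal(iface$residues_a, 1L)
  expect_equal(iface$residues_b, 1L)
})

test_that("burial classification is inclusive at the 5 % threshold", {
  expect_equal(classify_buried(4, 100), "buried")
  expect_equal(classify_buried(5, 100), "buried")
  expect_equal(classify_buried(20, 100), "exposed")
  expect_error(classify_buried(-1, 100), "negative")
})

test_that("atom roles separate backbone, beta carbon and side chain", {
  expect_equal(classify_atom_role("CA"), "main_chain")
  expect_equal(classify_atom_role("CB"), "c_beta")
  expect_equal(classify_atom_role("NH1"), "side_chain_specific")
  expect_equal(classify_atom_role(c("N", "O", "OXT")),
               rep("main_chain", 3))
  expect_equal(classify_atom_role("HB2"), "h_beta")
  expect_error(classify_atom_role("XX9"), "unknown atom name")
})

test_that("SASA of an isolated atom matches the closed-form sphere area", {
  st <- complex_structure(data.frame(
    chain_id = "A", residue_index = 1L, residue_type = "ALA",
    atom_name = "CB", element = "C", x = 0, y = 0, z = 0))
  s <- shrake_rupley_sasa(st, "A", probe_radius = 1.4, n_points = 960)
  expect_equal(s$sasa, 4 * pi * (1.70 + 1.40)^2, tolerance = 1e-6)
  # convergence: denser quadrature stays on the closed form
  s2 <- shrake_rupley_sasa(st, "A", n_points = 9600)
  expect_equal(s2$sasa, 4 * pi * 3.1^2, tolerance = 1e-9)
})

test_that("an atom enclosed by a neighbour shell has near-zero SASA", {
  # 26 neighbours on a 2.4 A lattice shell occlude the central atom
  sh <- expand.grid(x = c(-2.4, 0, 2.4), y = c(-2.4, 0, 2.4),
                    z = c(-2.4, 0, 2.4))
  at <- data.frame(chain_id = "A",
                   residue_index = seq_len(nrow(sh)),
                   residue_type = "GLY", atom_name = "CA", element = "C",
                   sh)
  st <- complex_structure(at)
  s <- shrake_rupley_sasa(st, "A")
  central <- which(sh$x == 0 & sh$y == 0 & sh$z == 0)
  expect_lt(s$sasa[s$residue_index == central], 1e-6)
})

test_that("peptide SASA agrees with a 10x denser quadrature within 2 %", {
  cfg <- scenario_config(seed = 21, chain_length = 50, interface_size = 3)
  st <- gen_toy_complex(cfg)$structure
  sub <- st$atoms[st$atoms$chain_id == "A" & st$atoms$residue_index <= 3, ]
  pep <- complex_structure(sub)
  coarse <- shrake_rupley_sasa(pep, "A", n_points = 960)
  fine <- shrake_rupley_sasa(pep, "A", n_points = 9600)
  expect_equal(coarse$sasa, fine$sasa, tolerance = 0.02)
})

test_that("PDB round trip preserves chains, sequences and coordinates", {
  cfg <- scenario_config(seed = 31, chain_length = 55, interface_size = 5)
  st <- gen_toy_complex(cfg)$structure
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(st, f)
  back <- read_complex_pdb(f, min_chain_length = 50)
  expect_identical(chain_sequences(back), chain_sequences(st))
  a1 <- st$atoms[order(st$atoms$chain_id, st$atoms$residue_index,
                       st$atoms$atom_name), ]
  a2 <- back$atoms[order(back$atoms$chain_id, back$atoms$residue_index,
                         back$atoms$atom_name), ]
  expect_equal(a1$x, a2$x, tolerance = 1e-3)
  expect_equal(a1$z, a2$z, tolerance = 1e-3)
})

test_that("PDB loading drops HETATM and short chains", {
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:60, 1:60, 1.5 * (1:60), 0, 0),
    sprintf("ATOM  %5d  CA  GLY B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            61:70, 1:10, 1.5 * (1:10), 10, 0),
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            71, 200, 0, 50, 0),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  st <- read_complex_pdb(f, min_chain_length = 50)
  expect_identical(st$chains, "A")
  expect_equal(nrow(st$atoms), 60)
})
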