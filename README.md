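# ppidup

Tools for asking how amino-acid change in protein–protein binding
interfaces relates to change in interaction specificity between duplicate
(paralogous) genes. The package is aimed at molecular-evolution and
structural-bioinformatics work on gene duplication: it covers the whole
chain from atomic coordinates to evolutionary statistics, and ships a
synthetic-data module with planted ground truth so every stage is testable
offline.

## What it computes

* **Interfaces from geometry.** Two atoms on different chains are in
  contact when their distance is below the sum of their van der Waals
  radii + 0.5 Å (closer than the radii sum = clash, still counted); all
  contacting residues form the interface. Shrake–Rupley SASA and a ≤ 5 %
  relative-accessibility burial rule classify residue exposure.
* **Shared interaction ratio.** For a duplicate pair with partner counts
  `n1`, `n2` sharing `s` partners on an evidence-filtered network
  (multiple-confidence mode keeps edges backed by ≥ 2 distinct studies):

  `SIR = 2s / (n1 + n2)`

* **Interaction-loss rate.** Assuming both daughters inherited the full
  ancestral interaction set,

  `rate = (l / a) · (1 / d)`

  losses per ancestral gene–partner interaction per Myr, with d = 100 Myr
  for whole-genome duplicates. Both the observed-network inference (biased
  downward by invisible double losses) and the unbiased planted-truth
  accounting are exposed.
* **Relative interface substitution rate.** Per-site substitution rate in
  interface columns over the rate elsewhere, gap columns excluded; pairs
  with ratio > 2 are flagged for exclusion.
* **Per-site selection (SLAC-style).** Fitch-parsimony ancestral codons,
  per-branch N/S decomposition with pathway averaging, Nei–Gojobori
  expected sites, a two-tailed binomial test per column
  (negative / neutral / positive at P < 0.05), and group comparisons via
  Kruskal–Wallis + pairwise Mann–Whitney with Benjamini–Hochberg
  correction.
* **Contact-preservation predictor.** An interface substitution that keeps
  ≥ 1 atom contact across the interface in the paralogue model predicts a
  maintained interaction; evaluation (precision / recall / F) takes
  conserved interaction as the positive class.

See `vignettes/interface-divergence.Rmd` for the full methods account.

## Worked example

```r
library(ppidup)

cfg <- scenario_config(seed = 11, n_pairs = 24, chain_length = 50,
                       interface_size = 8)

# a toy complex with a planted interface, recovered geometrically
cx <- gen_toy_complex(cfg)
identify_interface(detect_atom_contacts(cx$structure, "A", "B"))
#> ppi_interface A-B: 8+8 residues, 8 atom contacts (0 clashes)

# the full pipeline on a small synthetic cohort
run <- run_pipeline(cfg, n_selection_pairs = 8)
run
#> ppidup pipeline run (config 73c09323, 24 pairs, MC network)
#>   planted-interface recovery: 1.000
#>   loss rate (planted-truth):  3.83e-03 /PPI/Myr
#>   loss rate (network route):  2.19e-03 /PPI/Myr
#>   median relative interface rate: 0.567
#>   interface x interaction table:
#>            interaction
#> interface   conserved diverged
#>   conserved         2        4
#>   diverged          7        5
#>   predictor: precision=0.538 recall=0.778 F=0.636
```

Reading the output: all 24 planted interfaces were recovered exactly by
contact detection; the planted-truth loss estimate is this small cohort's
realised loss fraction per Myr, while the network route is lower because
losses hitting both members are invisible to it; interfaces accumulate
substitutions at roughly half the outside rate in this run; the 2×2 table
crosses interface divergence with interaction divergence; and the last
line scores the contact-preservation predictor against the simulated
interaction outcomes.

Evaluating the predictor on an explicit contingency — 14 of 35
conservative-substitution duplicates conserving their interactions, 85 of
105 divergent-interface duplicates diverging:

```r
evaluate_predictions(
  c(rep("conserved", 35), rep("diverged", 105)),
  c(rep("conserved", 14), rep("diverged", 21),
    rep("conserved", 20), rep("diverged", 85)))
#> classification (positive = conserved interaction):
#>   tp=14 fp=21 fn=20 tn=85
#>   precision=0.400 recall=0.412 F=0.406 (0.4)
```

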