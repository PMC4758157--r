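---
title: "Interface divergence and interaction specificity in duplicate genes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface divergence and interaction specificity in duplicate genes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

After a gene duplication both copies initially encode the same protein and,
by assumption, hold the same set of physical interaction partners. As the
copies diverge in sequence, some of their protein-protein interactions are
lost, and an open question is how tightly sequence change in the *binding
interface* is coupled to change in *interaction specificity*: are all
interface substitutions disruptive, or are many functionally equivalent?

`ppidup` implements the full analysis chain needed to study this on
protein complexes and interaction data:

1. geometric detection of binding interfaces from atomic coordinates,
2. evidence-filtered interaction networks and the shared interaction ratio
   (SIR) of duplicate pairs,
3. estimation of the interaction-loss rate per interaction per million
   years,
4. substitution accounting inside vs outside interfaces on paralogue
   alignments,
5. SLAC-style per-site selection classification on codon alignments, and
6. a predictor of interaction conservation from whether interface
   substitutions maintain atom contacts.

Real inputs of this kind (complex structures, curated interaction
databases, proteome alignments) are large, licensed or unstable over time,
so the package ships a first-class synthetic-data module that generates
every input with planted ground truth. All tests and the acceptance script
run offline against that truth.

## Interface geometry

Two atoms on different chains are **in contact** when their distance is
less than the sum of their van der Waals radii plus a margin, 0.5 Å by
default. Pairs closer than the radii sum alone are clashes and still count
as contacts, so small side-chain placement errors in modelled structures do
not delete interface residues. All residues owning at least one contacting
atom form the interface.

Choices that matter:

* **Radii table.** A single published heavy-atom set (Bondi values:
  C 1.70, N 1.55, O 1.52, S 1.80 Å) ships as `vdw_radii_bondi()` and can
  be replaced wholesale; the criterion itself is table-agnostic. Synthetic
  structures are heavy-atom only, so no hydrogen placement is performed;
  the H radius (1.20 Å) is included for completeness when real structures
  carry hydrogens.
* **Search.** The default contact search bins atoms on a grid with cell
  size equal to the maximum contact threshold and compares only the 27
  neighbouring cells, for expected linear time. Correctness is *defined*
  by the brute-force all-pairs scan (`method = "brute"`), and the test
  suite asserts exact equality of the two on every synthetic structure it
  generates.
* **Solvent accessibility.** Shrake-Rupley quadrature with a deterministic
  golden-angle point lattice (960 points/atom by default, probe 1.4 Å);
  burial is relative accessibility at or below 5 % of the Tien et al.
  theoretical maximum for the residue type. The quadrature converges to
  the closed-form sphere area as points increase, which the tests check on
  an isolated atom and against a 10x denser lattice on peptides.
* **Structure loading.** ATOM records only; ligands (HETATM) and chains
  shorter than 50 residues are dropped at load time; residues are
  renumbered 1-based and contiguous per chain so that structure numbering
  equals ungapped sequence position. PDB files with insertion codes are
  rejected rather than guessed at.

## Networks, SIR and the loss rate

Evidence records (`protein_a`, `protein_b`, `study_id`, source) are
filtered into either the **multiple-confidence (MC)** network -- an
experimental edge needs at least two *distinct* studies; duplicated study
ids count once -- or an **all** network keeping every experimental edge.
Structure-derived edges are merged in only where no experimental edge
already exists, so nothing is double-counted.

For a duplicate pair with partner sets of sizes `n1` and `n2` sharing `s`
partners,

    SIR = 2 s / (n1 + n2),

defined only when both members have at least one interaction. Interactions
with the paralogue itself and self-interactions count as ordinary
partners; the paralogue does not auto-match its sister. SIR is bounded in
[0, 1], symmetric in pair order, and 1 exactly when the partner sets are
identical.

The **loss rate** assumes both daughters inherited the full ancestral
interaction set and that divergence is loss-only:

    rate = (l / a) (1 / d)

with `l` lost gene-partner interactions, `a` ancestral gene-partner
interactions and `d` the time since duplication (100 Myr for whole-genome
duplicates). We count gene-partner interactions, not partners: with U the
union of the two current partner sets, `a = 2 |U|` and one loss per
member-partner interaction now absent. The alternative `a = |U|`
convention is available (`convention = "partner"`).

**Double losses are invisible** to this inference: a partner lost by both
members drops out of U entirely. Under an independent per-interaction loss
probability `p`, the observable loss fraction is `p/(1+p)` rather than
`p` -- a substantial downward bias at the default conditions
(`p = 6e-3 x 100 = 0.6` gives 0.375 vs 0.6). The package therefore
exposes both accounting routes in `estimate_loss_rate_cohort()`:

* `source = "network"` -- the union-based inference available on real
  data. The tests verify it lands on its derived expectation `p/(1+p)`,
  i.e. the bias is *measured*, not silently corrected.
* `source = "truth"` -- planted ancestral sets from the simulator, an
  unbiased binomial estimate used to verify that the estimator recovers
  the simulated rate.

## Substitution accounting and the relative interface rate

Alignment columns are labelled interface when either member's residue at
that column (by ungapped position) lies in any identified interface;
everything else -- core and surface alike -- is non-interface. Counting
conventions:

* a column with a gap in either member is a **gap column**, counted
  separately and never as a substitution;
* the per-region substitution *rate* excludes gap columns from both
  numerator and site totals;
* the **relative interface rate** is the interface rate over the
  non-interface rate; pairs with ratio > 2 are flagged for exclusion as
  likely erroneous estimates, and a zero non-interface rate makes the
  ratio undefined (flagged, not fabricated).

With exactly two sequences, a maximum-likelihood distance per region is a
monotone transform of mismatch density, so the package uses the counting
ratio directly rather than an ML fit; the quantity of interest is only the
*relative* rate. Pairwise Ka/Ks uses Nei-Gojobori counting: site counts
averaged over the two sequences, substitutions averaged over shortest
mutational pathways (stop-crossing pathways excluded), Jukes-Cantor
correction. Saturated proportions (possible on toy-sized inputs) are
reported as `Inf` rather than clipped.

For the interface/interaction contingency, a pair's **interface status**
is diverged when any interface column carries a substitution or -- by
default, configurable -- a gap, and its **interaction status** is diverged
when SIR < 1. Interface substitution matrices are undirected (21 symbols:
20 amino acids + gap), stored symmetrically, and split by interaction
status with per-cell proportions across the two statuses.

## Per-site selection

Ancestral codons are reconstructed by **Fitch parsimony over codon
states** with deterministic lexicographic tie-breaking (bottom-up:
intersection where non-empty, else union; top-down: keep the parent codon
when admissible, else the lexicographically smallest). Polytomies are
resolved deterministically in input order before reconstruction. Per
branch and column, codon differences are decomposed into single-nucleotide
steps averaged over shortest pathways and classified by the universal
code; expected site counts EN and ES come from Nei-Gojobori site counting
averaged over the codons observed at the column, scaled so
`EN + ES = N + S` (the scaling cancels in the test below, which only uses
the share `EN/(EN+ES)`).

Each column gets a **two-tailed binomial test** of the nonsynonymous count
among all substitutions with success probability `EN/(EN+ES)`; the
two-tailed p is `min(1, 2 min(lower, upper))` since no tail convention is
canonical. Below alpha = 0.05 a deficit of nonsynonymous change is
negative selection, an excess positive; otherwise -- including columns
with no substitutions -- neutral. Group comparisons use Kruskal-Wallis
across groups with pairwise Mann-Whitney tests and Benjamini-Hochberg
adjustment. Positive sites are computed but rare by construction and kept
out of the default group comparison.

This is a counting method on a single most-parsimonious reconstruction,
not an ML codon model: it is conservative at low divergence (multiple hits
are collapsed) and its calibration is checked empirically -- on
omega = 1 simulations the non-neutral call rate stays at or below alpha
within binomial bounds, and power increases monotonically as omega drops.

## The synthetic-data generators

`scenario_config()` fixes the emulated study conditions; its defaults are
the conditions used throughout the tests and the acceptance script:

| parameter | default | what it emulates |
|---|---|---|
| `n_pairs` | 204 | whole-genome duplicate cohort size with MC-network interaction data |
| `divergence_time` | 100 Myr | age of the whole-genome duplication |
| `loss_rate` | 6.0e-3 /PPI/Myr | interaction-loss rate of that cohort |
| `ancestral_degree_mean` | 3 | sparse per-duplicate interaction counts of a confidence-filtered network |
| `chain_length` | 60 | minimal complex chains above the 50-residue loading cutoff |
| `interface_size` | 10 | small contact patches |
| `p_sub_interface` / `p_sub_noninterface` | 0.15 / 0.20 | interfaces evolving at ~3/4 the outside rate |
| `tree` | fixed 8-taxon tree, ~6 substitutions/codon site total | deep yeast-scale divergence for selection inference |
| `site_classes` | omega 0.1 (constrained) and 1.0 (neutral) | negative selection in interfaces vs neutral drift |
| `p_preserve` | 0.5 | substitutions equally likely to keep or break their contact |
| `coupling` | 0.5 | contact preservation informative about, but not determining, interaction fate |

Generator construction, briefly:

* **Toy complexes.** Two parallel chains 16 Å apart, residues every
  4.5 Å, idealised side chains stacked perpendicular to the interface
  axis. At planted interface positions the distal side-chain atoms of the
  facing residues protrude to the midline and meet 0.2 Å above their radii
  sum -- inside the 0.5 Å margin, clash-free -- while every other
  inter-chain pair clears the threshold by more than 1 Å. Contact
  detection therefore recovers exactly the planted residues, which is an
  asserted property, not an approximation. These are geometric scaffolds,
  not folds: no packing, torsions or energies.
* **Paralogue models.** Substitutions are drawn per site at the region's
  density; a substituted interface residue keeps its protruding atom
  (contact preserved) or is withdrawn to the chain baseline (broken)
  according to a planted flag. Because heavy-atom radii differ by < 0.3 Å
  while the margin is 0.5 Å, a kept protrusion stays in contact whatever
  the new residue type. Deletions become gaps in the sequence and backbone
  stubs in the model.
* **Interaction loss.** Each pair starts with an identical ancestral
  partner set (Poisson around `ancestral_degree_mean`, truncated to >= 1);
  every gene-partner interaction is lost independently with probability
  `loss_rate x divergence_time`. Survivors are emitted with two distinct
  study ids so the MC filter keeps them. With `coupling > 0`, a random
  subset of pairs has its interaction outcome overridden to agree with the
  pair's contact-preservation truth; because this edits the realised loss
  process, loss-rate *estimation* scenarios use `coupling = 0`.
* **Codon alignments.** An omega-thinned mutation process: point
  mutations arrive as Poisson events along branches, synonymous changes
  always accepted, nonsynonymous accepted with the site class's omega,
  stops rejected. This is not a full codon model (no transition/
  transversion bias, no codon frequencies); it is adequate because the
  inference stage under test is itself a counting method, and the planted
  site classes are the ground truth being recovered.

What passing tests do **not** show about real data: synthetic interfaces
are unambiguous by construction, real contact patches are not; the loss
process ignores interaction gain entirely (the estimator cannot see gains,
and none are simulated); substitution placement is independent across
sites; and coupling between contact preservation and interaction fate is a
single dial, not a biophysical model.

## Contact-preservation predictor

An interface substitution that still makes at least one atom contact
across the interface in the paralogue model is predicted to maintain the
interaction; any substitution that does not -- including a deletion -- is
predicted to alter it. A pair is predicted diverged as soon as one
substitution fails. Evaluation takes **conserved interaction as the
positive class** (this makes the precision of a conservative-substitution
call the share of such pairs that really conserved their interactions) and
reports precision, recall and F-score with zero-denominator metrics set
to 0.

## Problem sizes and runtime choices

The shipped test-suite and acceptance-script sizes are: 50 complexes for
the contact-search oracle, 100 for interface recovery, 100 replicates of
204 pairs for loss-rate recovery, 1000 neutral sites for calibration,
300-site alignments per omega level for power, a 204-pair default pipeline
with the per-site selection scan run on 40 of those pairs, and 20 pooled
pairs of 500 sites per region for relative-rate recovery. These sizes keep
every stochastic check several standard errors wide of its bound while
remaining quick on one core.

## Known limitations

* Interaction gain is neither simulated nor estimable here; the loss rate
  is a loss-only quantity.
* The network-route loss estimate carries the `p/(1+p)` double-loss bias
  by design; use the planted-truth route on synthetic data, and read
  real-data estimates as lower bounds.
* Parsimony ancestors underestimate substitutions at high divergence, so
  per-site counts (and hence power) are conservative on long trees.
* The SASA routine treats the selected chain in isolation (unbound
  exposure); complex-context SASA is not computed.
* Real PDBs with insertion codes, altlocs beyond the first, or chimeric
  numbering are rejected rather than repaired.
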