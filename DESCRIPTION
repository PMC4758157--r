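Package: ppidup
Title: Interface Divergence and Interaction Specificity in Duplicate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how amino-acid change in protein-protein
    binding interfaces relates to change in interaction specificity between
    paralogous genes. Provides geometric interface detection from atomic
    coordinates (van der Waals contact criterion with a configurable margin),
    Shrake-Rupley solvent accessibility and burial classification,
    evidence-filtered interaction networks with the shared interaction ratio
    (SIR), estimation of the per-interaction loss rate after gene duplication,
    interface versus non-interface substitution accounting on paralogue
    alignments, SLAC-style per-site selection classification on codon
    alignments with Fitch parsimony ancestors, and a contact-preservation
    predictor of interaction conservation. A synthetic-data module generates
    minimal protein complexes, duplicate pairs, interaction networks and codon
    alignments with planted ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
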