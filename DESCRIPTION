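Package: famrecon
Title: Gene-Family Macroevolution by Duplication-Loss Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the macroevolution of gene families such
    as the chemokine signalling system: similarity-graph homology
    clustering at graduated stringency thresholds, gene-tree/species-tree
    reconciliation under weighted duplication-loss parsimony (LCA
    mapping, S/D event labelling, loss counting and optimal rooting),
    ancestral gene-complement reconstruction at species-tree nodes,
    branch support via transfer bootstrap expectation and classical
    bootstrap proportions, and candidate-sequence curation rules
    (cysteine-motif classification, transmembrane-domain filters). A
    birth-death gene-family simulator with ground-truth event logs makes
    every stage testable end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
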