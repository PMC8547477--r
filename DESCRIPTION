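Package: paddynet
Title: Co-Occurrence Networks and Assembly Processes of Paddy-Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for continental-scale paddy-soil microbiome analysis:
    alpha and beta diversity (including interaction-adjusted TINA indices),
    SparCC compositional correlation networks with bootstrap significance,
    two-stage Benjamini-Hochberg false discovery control and random-matrix-
    theory correlation thresholds, omission-score permutation tests for edge
    specificity, modularity and PageRank based keystone analysis, null-model
    quantification of community assembly (betaMNTD, betaNTI, Raup-Crick,
    normalized stochasticity ratio), and random-forest comparison of biotic
    versus environmental predictability of taxon abundances. Includes a
    synthetic community generator with full ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    igraph,
    picante,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
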