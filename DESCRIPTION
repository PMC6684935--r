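Package: supersat
Title: Phylogenomic Supermatrix Assembly and Substitution-Saturation Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building phylogenomic supermatrices from homology-search
    hits and diagnosing their quality. Implements e-value-windowed ortholog
    selection (best hit per taxon plus near-tied alternatives under
    length-dependent e-value ceilings), long-branch pruning of gene trees,
    occupancy-filtered concatenation with completeness accounting, Dayhoff
    six-state amino-acid recoding, saturation analysis by regression of
    uncorrected p-distances on tree patristic distances, and a bipartition
    maximum-frequency-difference convergence statistic for posterior tree
    samples. A seeded synthetic-data generator evolves gene families along a
    known species tree with rate variation, missing taxa, decoy paralogs and
    long-branch tips so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
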