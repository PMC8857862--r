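Package: mitonet
Title: Mitochondrial DNA Mutation-Cancer Networks and Overlap Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrating somatic and homoplasmic mitochondrial DNA
    variant cohorts across cancer types. Merges per-sample variant tables,
    annotates positions to named regions of the circular rCRS mitochondrial
    genome (including the wrapped D-loop/control region), builds the bipartite
    mutation-cancer association network, and tests pairwise cancer-type
    variant-set overlap with the Jaccard index and randomization-based
    empirical p-values. Ships transcribed summary fixtures from a published
    gastric-cancer/pan-cancer comparison and a synthetic-cohort generator with
    planted overlaps so every pipeline stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    xml2
Config/testthat/edition: 3
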