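Package: exonbaits
Title: Exon-Based Target-Enrichment Bait Design and Capture Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing clade-specific hybridization-capture bait
    sets from single-copy nuclear gene alignments and for evaluating the
    resulting sequence capture. Implements the gene- and exon-level filtering
    cascade (minimum length, taxon coverage, mean pairwise identity bounds),
    cross-reference exon selection, fixed-length probe tiling at a chosen
    tiling density with quality control, overlap analysis against external
    bait panels, per-sample recovery statistics with column summaries and
    heatmap matrices, alignment occupancy trimming and informativeness
    statistics (variable and parsimony-informative sites), same-taxon tip
    masking on gene trees, per-branch quartet concordance between a species
    tree and gene trees, and seeded simulators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
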