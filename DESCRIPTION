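Package: resevar
Title: Genome-Wide Variation Analysis for Resequenced Inbred Rice Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for comparative genome-wide variation
    analysis of resequenced inbred crop lines against a common reference
    genome. Provides a simplified Bayesian diploid genotype caller with
    quality- and read-support filters for SNPs, short insertions/deletions
    (up to 5 bp) and structural variants; multi-sample shared / different /
    unique locus classification under a coverage-eligibility rule with
    inclusion-exclusion union accounting; strand-aware coding-effect
    annotation including large-effect categories (premature stop, start-codon
    loss, stop-codon loss); sliding-window variation-frequency scans with
    high/low-variation region calling; SNP p-distance matrices with
    neighbor-joining trees; per-chromosome summary tables, heterozygosity
    estimation and GO/PFAM tallies. A fully seeded synthetic-data generator
    produces toy genomes, gene models, coverage masks, variant sets and
    site-level read evidence with a known truth table so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    vctrs,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
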