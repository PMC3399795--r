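Package: polymir
Title: Small RNA Profiles and miRNA Expression Additivity in Hybrid Polyploid Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative small RNA-seq analysis toolkit for hybrid polyploid
    systems in which individuals carry different dosages of two parental
    genomes (e.g. PP and AA diploids, PA diploid hybrids, PAA triploid
    hybrids). Implements read filtering and tag collapsing, pairwise
    common/exclusive sequence comparison, hierarchical annotation of tags
    against a categorized reference (rRNA and other structural RNAs over
    miRNA over repeat over exon over intron), miRNA expression as the
    proportion of total miRNA reads per library, crescent-curve log-ratio
    comparisons with up/down chi-square classification, and dosage-weighted
    mid-parent additivity analysis of hybrid expression. Ships a synthetic
    library generator with known ground truth so the whole pipeline is
    testable end to end without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    yaml,
    jsonlite,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
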