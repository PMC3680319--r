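Package: meklchip
Title: Tissue-Specific Differentially Methylated Region Analysis for
    MBD-Enrichment Methylation Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel methylation tiling arrays in
    which an MBD-enriched (methylated) DNA fraction is co-hybridized with
    input DNA, as in CHARM-style experiments. Provides hybridization quality
    scores against anti-genomic background probes, within-sample loess dye
    correction on control probes, between-sample quantile normalization of
    log2 relative methylation, genome-weighted (triangular kernel) smoothing
    within probe clusters, per-probe t-statistics and aggregation of
    significant probe runs into tissue-specific differentially methylated
    regions (T-DMRs), CpG observed/expected and local weighted CpG density
    annotation, concordance classification of regions between high-input and
    low-input arrays against a shuffled null, and QPCR fold-enrichment QC.
    A seedable synthetic-data generator emulates CpG-heterogeneous genomes,
    CpG-driven probe tilings with control and anti-genomic probes, planted
    tissue-specific methylation differences, intensity-dependent dye bias,
    and input-amount-dependent noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    limma,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
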