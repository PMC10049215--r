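Package: methexpr
Title: Integrated DNA Methylome and Transcriptome Analysis of Staged
    Developmental Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for joint whole-genome bisulfite
    sequencing (WGBS) and RNA-seq analysis of a staged developmental
    series. Computes per-CpG methylation levels from Bismark-style
    cytosine reports with coverage filtering, characterizes the global
    methylome (context composition, bimodal level histograms, sample
    correlation, PCA, genomic-feature stratification), calls
    differentially methylated regions (DMRs) between stages over genome
    tiles with an exact conditional test, normalizes counts to TPM and
    calls differentially expressed genes (DEGs) with a negative-binomial
    Wald test, soft-clusters DEG trajectories by fuzzy c-means, builds
    metagene methylation profiles stratified by expression, and
    identifies promoter-negative genes (PNGs) and methylation-regulated
    DEGs (DM-DEGs) by promoter-methylation/expression correlation. A
    synthetic-data module generates miniature genomes with planted
    ground truth (DMRs, DEGs, DM-DEGs) for benchmarking and recovery
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
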