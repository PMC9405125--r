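Package: consensusCNVR
Title: Dual-Caller CNV Region Consensus Analysis for SNP Array Intensity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls copy number variants (CNVs) from SNP-array Log R Ratio and
    B Allele Frequency profiles with a distance-aware copy-number hidden
    Markov model scored by log10 Bayes factors, applies per-sample quality
    control (LRR standard deviation, BAF drift) and confidence filtering,
    and builds consensus CNV regions (CNVRs) across individuals, callers,
    and population groups: per-group merging of overlapping calls,
    representativeness filtering, cross-caller intersection, and cross-group
    specificity classification. Final regions can be annotated against gene
    and QTL intervals with one-sided Fisher term enrichment and cluster
    enrichment scores. Includes a synthetic cohort generator that simulates
    marker maps, spiked copy-number events, and per-sample intensity
    profiles so that the whole pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
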