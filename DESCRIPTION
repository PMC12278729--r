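Package: triocnv
Title: Trio Genome Read-Depth CNV Discovery and Variant Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Read-depth copy-number-variant discovery and small-variant
    triage for trio whole-genome sequencing. Partitions the genome into
    fixed-width bins, normalises per-sample coverage as RPKM, compares a
    test sample against the median of a control panel as a log2-ratio
    track, segments the track with circular binary segmentation using a
    permutation significance test, converts segments into typed CNV calls,
    and filters the calls through a cascade of shared-in-affected-siblings,
    segmental-duplication, SNV-heterozygosity/read-pair-evidence, and
    population structural-variant frequency rules. Candidate deletions are
    refined to base-pair breakpoints by split-read clustering with
    microhomology-aware left alignment, and trio small variants are
    filtered by consequence, population frequency and REVEL score before
    classification under homozygous, compound-heterozygous and
    shared-heterozygous inheritance models. Includes a synthetic-data
    module that generates trio coverage profiles with engineered CNVs,
    breakpoint-spanning reads, and annotated trio variant tables so the
    whole pipeline can be exercised end to end without protected data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
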