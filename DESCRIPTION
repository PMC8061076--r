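Package: methscape
Title: Smoothing-Based Differential and Variable Methylation Analysis for
    Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@methscape.org",
           role = c("aut", "cre"))
Description: Tools for region-level analysis of whole-genome bisulfite
    sequencing (WGBS) methylomes across grouped samples. Implements
    coverage-weighted local-polynomial smoothing of per-cytosine
    methylation fractions (CpG and non-CpG contexts), F-statistic calling
    of differentially methylated regions (DMRs) and large blocks with
    permutation-based family-wise error rate control, detection of
    variably methylated regions (VMRs) via per-tissue standard-deviation
    cutoffs with Cook's-distance outlier filtering and cross-tissue
    sharing classification, and CpX-resolution enrichment of region sets
    in genomic features (log2 odds ratios with exact tests). Includes a
    seeded beta-binomial simulator of multi-tissue, multi-donor WGBS
    count data with planted DMRs, blocks, VMRs, genotype-driven regions
    and outlier samples, emitting Bismark-style cytosine reports and a
    machine-readable truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
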