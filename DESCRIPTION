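Package: divscan
Title: Sliding-Window Selective Sweep and Local Adaptation Scans from
    Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome scans for selective sweeps and local adaptation from
    multi-sample variant calls. Reads biallelic SNP genotypes from VCF into
    a SummarizedExperiment-derived container, applies a hard-filter chain
    (depth, mapping quality, indel proximity, Hardy-Weinberg equilibrium,
    site quality, quality-by-depth, observed heterozygosity), computes
    sliding-window nucleotide diversity, Watterson's theta, Tajima's D,
    Weir-Cockerham FST and log2 diversity ratios, calls outlier regions by
    joint empirical-tail thresholds, attaches overlapping gene models, and
    tests term enrichment of candidate genes with a chi-squared test. A
    coalescent and Balding-Nichols simulator generates calibrated synthetic
    datasets with known sweep and differentiation truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
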