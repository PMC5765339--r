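Package: tri21cnv
Title: Copy Number Variant Discovery and Association on Trisomic Chromosome 21
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting and testing copy number
    variants (CNVs) on chromosome 21 in trisomy 21 (Down syndrome) cohorts
    assayed by array comparative genomic hybridization against a trisomic
    reference. Includes a ground-truth simulator for trisomic aCGH cohorts,
    multi-tier array and probe quality control, dual-algorithm CNV calling
    (sparse backward-elimination segmentation and an interval-score shift
    caller) with concordance intersection, calibration of the segmentation
    threshold via trisomy-specific frequency bounds, post-call filtering and
    catalog validation by reciprocal overlap, SNP-based population
    stratification, and permutation-based burden and association testing with
    one-sided Fisher and Mann-Whitney kernels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
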