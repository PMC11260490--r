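Package: tfcrkit
Title: Calling and Comparative Analysis of Transcription Factor Binding
    Site Clustered Regions
Version: 0.1.0
Authors@R:
    person("TFCR", "Maintainers", email = "maintainers@tfcrkit.org",
           role = c("aut", "cre"))
Description: Identifies transcription factor binding site clustered
    regions (TFCRs) from motif occurrences in open chromatin by Gaussian
    kernel density estimation, scores their strength and complexity, and
    analyses them across developmental stages and species: stable/gained/
    lost dynamics with a permutation test, genome-size-normalised top and
    bottom TFCR selection, a RegulatoryScore statistic measuring the
    synchronisation of promoter-TFCR complexity with gene expression,
    cross-species clustering and hypergeometric enrichment, and an
    explainable gradient-boosted tree regressor with exact TreeSHAP
    attributions over one-hot sequence plus distance features. Includes a
    seeded synthetic-data generator emulating promoter-enriched TFBS
    clusters, multi-stage gain/loss dynamics with a zygotic-genome-
    activation burst, and complexity-coupled expression, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    digest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
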