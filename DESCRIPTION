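Package: svelt
Title: Somatic Structural Variant and Copy Number Analysis from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of somatic structural variants (SVs) and somatic
    copy-number aberrations from long-read tumor (with or without matched
    normal) alignments. Putative breakpoints are discovered from split reads,
    gapped alignments and long soft-clips, clustered with type-specific
    windows, encoded as 70 covariates and filtered with a random-forest
    classifier whose calls carry Mondrian conformal prediction confidence.
    Read depth is segmented with permutation-tested circular binary
    segmentation; tumor purity is estimated from B-allele frequencies at
    loss-of-heterozygosity blocks and ploidy fitted by grid search. Includes
    replicate- and phasing-based benchmarking utilities and seeded synthetic
    data generators so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    ranger,
    pROC,
    jsonlite,
    Rcpp,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
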