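Package: footvar
Title: Predicting Regulatory Variants that Alter Transcription Factor
    Binding from DNase-Seq Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for annotating non-coding genetic variants by their
    predicted effect on transcription factor (TF) binding.  Implements a
    CENTIPEDE-style two-component mixture model for DNase-seq cut profiles
    at motif matches (multinomial footprint shape, negative-binomial read
    totals, logistic position-weight-matrix score hyperprior, fitted by
    EM), motif scanning and recalibration, allele-aware classification of
    footprint-SNPs into effect- and switch-SNPs, a beta-binomial joint
    genotyping and allele-specific hypersensitivity (ASH) test with
    partitioned Storey q-value FDR control, motif-wise ASH enrichment
    ratios, a modified McDonald-Kreitman selection score on binding sites
    with derived-allele-frequency spectra, and a fully deterministic
    synthetic-data generator for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    withr,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
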