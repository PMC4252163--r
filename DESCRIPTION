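Package: twinDMP
Title: Differential Methylation Analysis for Discordant Monozygotic Twin Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Infinium-style DNA methylation array data
    from monozygotic twin pairs discordant for a phenotype. Implements
    detection-p-value and bead-count quality control, SNP-control-probe
    monozygosity checks, stratified background adjustment and quantile
    normalization of type I and type II probe intensities, summed-rank
    prioritization of differentially methylated positions combining paired
    t-test significance with effect magnitude, two-group methylation variance
    heterogeneity analysis, gap-based differentially methylated region calling,
    nearest-TSS annotation, and a synthetic twin-pair data generator with
    known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
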