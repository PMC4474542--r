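Package: methylreg
Title: Prediction of Promoters and Enhancers from DNA Methylation Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts regulatory regions (promoters and enhancers) from
    whole-genome DNA methylation profiles. For each candidate region five
    methylation-derived features are computed against random background
    regions matched by relative genomic position: mean methylation level,
    cross-cell-line methylation variance, methylation autocorrelation
    between neighbouring mCpG sites, CpG density, and the enrichment
    significance of centered-CpG 8-mer sequence motifs. Regions are
    classified with a polynomial-kernel support vector machine under
    stratified cross-validation and features are ranked by information
    gain. A synthetic-data generator produces multi-cell-line methylomes,
    genome sequence, gene annotation and expression tables with the
    statistical structure of real regulatory methylomes so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
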