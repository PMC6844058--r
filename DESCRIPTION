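Package: methylDissect
Title: Virtual Methylome Dissection with Bipolar Methylation Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-reference-free deconvolution of bulk DNA methylomes.
    Detects putative cell-type-specific methylated (pCSM) loci from
    read-level bisulfite data via a beta-mixture bipolarity test on 4-CpG
    segment patterns, condenses them into eigen-pCSM loci through signed
    co-methylation network modules and PCA, and decomposes loci-by-sample
    methylation matrices into latent methylation components with
    simplex-constrained, binarization-regularized nonnegative matrix
    factorization. Includes a synthetic-methylome simulation and scoring
    framework (RMSE, MAE, component matching) for benchmarking recovery of
    known cell mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
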