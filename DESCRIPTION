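Package: nbsupport
Title: Net Bootstrap Support for Phylogenomic Clade Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clade confidence for concatenated (superalignment) phylogenomics
    using little-bootstrap site subsampling with upsampled replicates.
    Computes per-subsample bootstrap confidence limits (bcl), the Net
    Bootstrap Support (NBS, the mean of the bcl distribution), a median-based
    estimate of Felsenstein bootstrap support (FBS), and the overconfidence
    (OC = FBS - NBS) of standard superalignment bootstrapping, with an
    adaptive stopping rule on the root mean squared deviation of NBS between
    iterations.  Flags clades affected by phylogenetic heterogeneity through
    unimodality tests of bcl distributions (a dip statistic with Monte Carlo
    calibration and a Silverman critical-bandwidth mode count).  Includes a
    built-in weighted-distance neighbor-joining engine, an adapter for
    external maximum-likelihood programs, and a sequence simulator for
    gene-tree heterogeneity, estimation-error and missing-data regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
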