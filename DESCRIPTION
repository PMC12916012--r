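Package: hdlc
Title: Likelihood-Based Testing of Regional Genetic Colocalization from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements HDL-C, a constrained likelihood-ratio test of
    regional genetic colocalization between two traits. The test decides
    whether the local genetic correlation within a genomic region exceeds
    a user-chosen threshold, using only per-variant GWAS Z-scores and a
    linkage-disequilibrium (LD) reference for the region. The bivariate
    Gaussian likelihood of the Z-scores is evaluated in the eigen-space of
    the LD matrix; the null hypothesis bounds the local genetic covariance
    and the resulting statistic follows a chi-bar-square mixture. The
    package also provides summary-statistics harmonization utilities, a
    simulation framework (individual-level and direct summary-level modes)
    for assessing operating characteristics, and rank-based evaluation
    metrics (ROC/AUC, TPR at fixed FPR, rediscovery rate, null-calibration
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
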