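Package: regmarker
Title: Robust Brain-Region Marker Genes by mRMR Ranking and
    Cross-Individual Incremental Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genes whose expression robustly discriminates the
    brain stem, cerebellum and cerebral cortex across individuals. Expression
    features are ranked per individual by minimum-redundancy
    maximum-relevance (mRMR) mutual information on three-state discretized
    intensities; a linear soft-margin support vector machine trained by
    sequential minimal optimization (SMO), extended to three classes by
    one-vs-one voting, is then evaluated on growing feature-list prefixes
    against every other individual's samples (revised incremental feature
    selection). An inflection-point rule selects a compact feature set per
    accuracy curve, prefix sets are intersected per training individual, and
    a cross-individual frequency table ranks consensus marker genes. A
    synthetic cohort generator with planted region-discriminative genes
    makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite,
    withr
Config/testthat/edition: 3
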