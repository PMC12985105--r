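Package: abseqde
Title: Dual-Track Consensus Differential Expression for Small Multimodal
    Single-Cell Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression and cell-type composition analysis for
    targeted single-cell RNA plus surface-protein (AbSeq/ADT) panels measured
    on small clinical cohorts. Implements a per-cell negative binomial mixed
    model with a subject random intercept (fitted by adaptive Gauss-Hermite
    quadrature), a subject-level pseudobulk regression track, and a
    direction-concordant consensus rule that declares a feature differential
    only when the mixed-model q-value passes FDR, the pseudobulk p-value is
    below 0.05, and both tracks agree in sign. Also provides logit-scale
    cell-type composition tests, one-at-a-time clinical-confounder robustness
    scoring via signed -log10 p correlations, panel-background Fisher geneset
    enrichment, quality-control filters for targeted panels, and a calibrated
    multimodal count simulator with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmmTMB,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
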