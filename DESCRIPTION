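Package: coxenrisk
Title: Cross-Cell-Type Atherogenic Risk Prediction from Leukocyte Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates multi-gene predictors of atherogenic risk from
    leukocyte expression profiles. Implements the full pipeline: per-probe
    two-sample t-test discovery with Benjamini-Hochberg q-values and signed fold
    changes, functional triage of biomarkers against an annotation table, COXEN
    (co-expression extrapolation) selection of genes whose co-expression network
    is concordant between cell types, a standardize/PCA/LDA posterior-probability
    risk classifier, and ROC evaluation with Youden-optimal cutoffs and confusion
    metrics. Includes a latent-factor synthetic cohort generator emulating
    multi-cell-type familial-hypercholesterolemia case-control designs so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
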