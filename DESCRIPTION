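Package: amypath
Title: Subtype and Stage Inference for Biomarker Pathway Heterogeneity in
    Amyloid-Positive Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising heterogeneity of biomarker progression
    among CSF amyloid-positive individuals. Provides Gaussian-mixture
    estimation of the amyloid positivity cut-point, control-referenced
    (optionally covariate-corrected) z-score normalisation of cognitive,
    fluid and volumetric markers, a z-score event-based subtype-and-stage
    model fitted by greedy ascent and Metropolis-Hastings sampling over
    constrained event orderings, cross-validated model selection (CVIC),
    per-subject subtyping and staging, positional variance diagrams,
    post-hoc subtype evaluation, and a seeded synthetic cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
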