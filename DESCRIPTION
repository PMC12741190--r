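Package: lifespanomics
Title: Lifespan Plasma Metabolomics and Lipidomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for cross-sectional plasma metabolomics and
    lipidomics across the human lifespan: total-sum and median-ratio
    normalization with nonzero and QC-CV filtering, group-wise differential
    expression with Benjamini-Hochberg correction, pathway
    over-representation, per-feature linear age models with a sex covariate,
    LOESS age-trajectory fitting and hierarchical clustering, sliding-window
    differential expression (DE-SWAN) with peak detection, lipid shorthand
    parsing with chain-length and saturation analytics, principal variance
    component analysis, metabolite-lipid Spearman correlation networks, and
    a multi-stage elastic-net aging clock with broken-stick model reduction
    and a cross-validated biomarker panel. Includes a synthetic cohort
    generator with known ground-truth age trajectories so every stage is
    testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    mclust,
    optparse
Config/testthat/edition: 3
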