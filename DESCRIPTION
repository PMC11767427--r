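Package: osteowarn
Title: Early-Warning Analysis of Osteopenia from Metabolomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reference-anchored single-sample edge-network analysis for
    detecting the critical (tipping-point) stage in the progression from
    normal bone mass through osteopenia to osteoporosis. Builds
    single-sample co-expression scores (sPCC) against a healthy reference,
    fourth-order edge-pair scores (shPCC), and a per-sample composite
    early-warning index (sCI) over candidate metabolite modules, and
    surrounds the core method with differential-metabolite trend testing
    (Jonckheere-Terpstra, Wilcoxon), random-forest biomarker selection with
    paired AUC comparison, a simplified weighted-correlation-network
    module-trait analysis, and quasi-Bayesian causal mediation for binary
    outcomes. Includes a synthetic three-stage cohort generator with
    planted dynamic-network-biomarker structure so every stage of the
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    pROC,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
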