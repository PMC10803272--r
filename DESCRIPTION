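Package: bprf
Title: Burden of Proof Evidence Scoring for Dichotomous Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analytic evidence scoring for dichotomous risk factors in
    the Burden of Proof framework: ingestion and validation of
    observation-level relative-risk extraction tables, a prioritization
    cascade that reduces each study's reported effect sizes to an analysis
    set, standard-error inflation for repeated non-mutually-exclusive
    exposure groups, trimmed mixed-effects meta-regression in log
    relative-risk space with study-level random effects, step-wise
    Lasso selection of binary bias covariates, conservative uncertainty
    intervals inclusive of between-study heterogeneity, the Burden of
    Proof Risk Function (BPRF), risk-outcome scores and star ratings,
    Egger's regression diagnostics for publication bias, and a synthetic
    extraction-table generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
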