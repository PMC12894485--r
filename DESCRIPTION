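Package: csfmsval
Title: Validation of Cerebrospinal-Fluid Molecular Tests for Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate cerebrospinal-fluid (CSF) proteomic molecular
    tests for multiple sclerosis (MS) in multicenter cohorts. Implements the
    full validation workflow: a seeded synthetic-cohort generator with
    class-dependent protein signal, age/sex effects and a latent severity
    coupled to disability progression; age/sex-adjusted log-ratio feature
    engineering over configurable protein panels; random-forest diagnostic
    (MS vs non-MS), staging (relapsing-remitting vs progressive MS) and
    severity models with a fixed probability cutoff; ROC inference from
    first principles (Mann-Whitney AUROC, stratified bootstrap confidence
    intervals, Mason-Graham significance, paired DeLong comparison, confusion
    metrics); and a prognostic chain converting a CSF-predicted severity score
    through a CombiWISE progression slope into a predicted follow-up EDSS,
    with explained-variance gain evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
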