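Package: ldlconcord
Title: LDL Cholesterol Estimating Equations and Clinical Concordance Analysis
Version: 0.1.0
Authors@R: person("ldlconcord", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the three LDL cholesterol estimating equations in
    routine laboratory use (Friedewald, Martin-Hopkins with its stratified
    adjustable-factor lookup, and Sampson-NIH), together with the machinery
    needed to audit the clinical consequences of switching between them:
    unit conversion, guideline treatment-category assignment, triglyceride
    stratification, percentage-difference summaries, Cohen's kappa on
    category cross-tabulations, Wilcoxon/Spearman/Bland-Altman agreement
    statistics, a reproducible synthetic lipid-cohort generator with known
    ground truth, and an end-to-end filtering/analysis/reporting pipeline
    with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
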