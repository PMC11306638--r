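Package: aromawise
Title: Matched Case-Control and Epigenetic Analysis of Prenatal BPA Exposure
    and Aromatase Pathway Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene-environment interaction between prenatal
    bisphenol A (BPA) exposure and genetic aromatase (CYP19A1) pathway
    activity in birth-cohort data. Provides urinary exposure preprocessing
    (specific-gravity correction, limit-of-detection policy, quantile
    dichotomization) and tolerable-daily-intake arithmetic; unweighted and
    eQTL-weighted CYP19A1 genetic activity scores; a stratified, iterative
    nearest-neighbour matched case-control design builder; a conditional
    logistic regression engine fit by Newton-Raphson on the conditional
    likelihood; population attributable fraction with a set-level bootstrap;
    ROC/AUC and diagnostic likelihood ratios; promoter CpG-window methylation
    association and product-of-coefficients mediation with percentile
    bootstrap; and direction-concordance tests for opposed pathway
    perturbations. A synthetic-cohort generator reproduces the statistical
    structure these analyses assume, so the full chain is testable without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
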