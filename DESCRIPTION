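Package: fickco
Title: Indirect-Fick Cardiac Output Estimation and Method-Comparison Statistics
Version: 0.1.0
Authors@R: person("RHC", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes indirect-Fick cardiac output from right heart
    catheterization oximetry using four published oxygen-consumption (VO2)
    approximation formulas (Krakau, LaFarge, Dehmer, Bergstra), together with
    body surface area, arteriovenous oxygen content difference, cardiac index
    and pulmonary vascular resistance. Provides method-comparison statistics
    against a thermodilution reference: Bland-Altman limits of agreement,
    Critchley percentage error with the 30% acceptability rule, ratio-based
    concordance classification, Pearson correlation with Fisher-z confidence
    intervals, and Cohen's kappa between classifications. Includes a
    synthetic-cohort generator with a known-truth multiplicative disagreement
    model, and a command-line pipeline that validates a cohort CSV, runs every
    comparison and writes tables, plot coordinates and a JSON summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
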