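Package: abetascreen
Title: Plasma Amyloid-Beta and APOE Genotype Pre-Screening for Amyloid PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for evaluating plasma amyloid-beta 1-42 combined with APOE
    genotype as a pre-screening cascade for amyloid PET imaging in suspected
    early-stage Alzheimer's disease. Provides a synthetic cohort generator
    calibrated to published genotype frequencies, genotype-conditional PET
    positivity rates and PET-status-conditional plasma biomarker moments;
    empirical ROC construction with Youden-index cut-off selection on the
    reciprocal-marker scale; genotype-gated screening pathway rules and their
    diagnostic-accuracy evaluation; exact integer reconstruction of latent
    2x2 confusion matrices from rounded published metrics; and in-package
    logistic risk models with DeLong comparison of correlated AUCs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
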