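Package: predictval
Title: External Validation Toolkit for the PREDICT Breast Cancer
    Prognostic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the PREDICT v2.2/v3.0 breast-cancer prognostic
    engine (per-patient yearly cumulative breast-cancer-specific and
    other-cause mortality, with adjuvant treatment effects, driven by
    versioned JSON coefficient files), a registry-cohort preparation
    pipeline (eligibility, biomarker and treatment mapping, subgrouping,
    horizon restriction), a synthetic cohort generator with known
    ground-truth risk structure, and the validation statistics used to
    assess prognostic models under competing risks: smooth calibration
    curves from piecewise-exponential Poisson generalized additive
    models, the integrated calibration index (ICI), inverse probability
    of censoring weighted time-dependent AUC, and paired percentile
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
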