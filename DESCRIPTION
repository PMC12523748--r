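Package: spectraef
Title: Arterial Enhancement Fraction Markers from Dual-Layer Spectral CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives quantitative dual-layer spectral CT markers for thyroid
    micronodules - the spectral Hounsfield-unit curve slope (lambda-HU),
    carotid-normalized iodine concentration (NIC) and effective atomic number
    (NZeff), and the arterial enhancement fraction computed either from
    blended-image attenuation (AEF_S) or from iodine maps (AEF_D) - and
    evaluates their diagnostic performance for distinguishing malignant from
    benign micronodules. Provides a seeded synthetic-cohort generator
    parameterized by published median/IQR summaries, normality-gated group
    comparisons, Bland-Altman and rank-correlation agreement analysis,
    forward-selection logistic regression with collinearity diagnostics, and
    ROC analysis with DeLong confidence intervals, Youden-index cutoffs and an
    unnecessary-biopsy-rate panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
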