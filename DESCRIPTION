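Package: t21screen
Title: First-Trimester Trisomy 21 Screening Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Build and evaluate first-trimester trisomy 21 screening risk
    models from maternal serum markers (PAPP-A, free beta-hCG, AFP-L2) and
    nuchal translucency. Provides multiple-of-median (MoM) normalization
    with gestational-age and maternal-weight median curves, a maternal-age
    prior risk, class-conditional multivariate Gaussian likelihood-ratio
    scoring over all marker subsets, ROC/Youden/diagnostic-table
    evaluation, IDI/NRI model-improvement statistics, and a calibrated
    synthetic cohort generator so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
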