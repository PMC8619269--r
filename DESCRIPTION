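Package: thalscreen
Title: Reticulocyte Cell-Population-Data Screening for Alpha- vs Beta-Thalassaemia Trait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a composite haematology discriminant (the alpha-beta
    score: median lower-median-angle light scatter of reticulocytes times red-cell
    distribution width, minus mean corpuscular haemoglobin) for separating
    alpha- from beta-thalassaemia trait in carrier screening, together with the
    machinery needed to develop and validate such a discriminant: empirical ROC
    curves with Mann-Whitney AUC and DeLong or bootstrap confidence intervals,
    Youden-style cutoff selection, parameter shortlisting, 2x2 diagnostic
    accuracy statistics with Wilson, Clopper-Pearson or Wald intervals, and a
    seeded synthetic cohort generator parameterised by published group summary
    statistics so every pipeline stage is testable without analyzer exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
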