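Package: pedfl
Title: Fatty Liver Prediction Models for Obese Children and Adolescents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Development and internal validation of multivariable logistic
    prediction models of ultrasonographic fatty liver in pediatric obesity.
    Provides degree-2 fractional-polynomial function selection with a closed
    testing procedure, bootstrap inclusion fractions for variable selection,
    the two published BMI- and WC-based scoring equations as immutable model
    cards, discrimination and likelihood-based fit measures, the three-level
    (mean/weak/moderate) calibration hierarchy with bootstrap confidence
    intervals, Riley minimum sample-size criteria for binary-outcome models,
    and a Gaussian-copula synthetic cohort generator calibrated to published
    quartile summaries and rank-correlation tables so the whole workflow is
    reproducible without access to the clinical dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
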