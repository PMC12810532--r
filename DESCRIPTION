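Package: echorules
Title: Rule-Based Identification and Grading of Aortic Stenosis from
    Echocardiogram Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A population-level screening engine for aortic stenosis (AS)
    built on routinely collected echocardiography data. Combines a
    rule-based lexicon over free-text report conclusions (severity
    language, negation, leaflet restriction, prosthetic-valve mentions)
    with quantitative grading of aortic valve area, mean transvalvular
    gradient and peak velocity against guideline threshold tables, using a
    qualitative-over-quantitative hierarchy in which the reading
    echocardiographer's written interpretation resolves discordance.
    Includes the validation protocol for the engine (stratified
    adjudication sampling, binary and half-grade concordance,
    sensitivity/specificity, misclassification regression), a
    treatment-disparity analysis suite (univariate comparisons and
    multivariable logistic regression for receipt of aortic valve
    replacement), and a fully labelled synthetic-cohort generator so the
    entire pipeline is testable without protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
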