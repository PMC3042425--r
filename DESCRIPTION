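Package: nestedAUC
Title: Size and Power of Tests for the Incremental Value of a New Marker
    in Nested Logistic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo machinery for comparing three tests of whether a
    new biomarker adds predictive information to an established marker in
    a nested logistic-regression setting: the likelihood-ratio test, the
    Wald test, and the DeLong paired test applied to areas under the ROC
    curves of the two models' in-sample linear predictors.  Includes a
    synthetic-data generator with known true coefficients, maximum-
    likelihood nested logistic fits, a structural-components (placement
    value) implementation of the DeLong test, and a simulation runner that
    produces empirical rejection-rate tables over a grid of effect sizes,
    marker correlations, sample sizes and outcome prevalences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
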