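Package: vepcal
Title: Gene- and Domain-Aware Calibration of Variant Effect Predictors
    into ACMG/AMP Evidence Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts variant effect predictor (VEP) scores for missense
    variants into calibrated posterior probabilities of pathogenicity and
    ACMG/AMP Bayesian evidence points. Implements the exponential
    likelihood-ratio point scale with prior-dependent thresholds, eleven
    posterior-calibration methods with prior-shift correction and
    conservative out-of-bag bootstrap envelopes, a simulation engine over
    parametric score-distribution families with closed-form true
    posteriors, evidence-point miscalibration metrics, a data-adaptive
    three-stage calibration-method selection procedure with gene
    eligibility rules, positive-unlabeled class-prior estimation from a
    distance-removal curve, and protein-domain aggregation by
    Jensen-Shannon distance clustering with dynamic tree splitting.
    Includes interval likelihood-ratio evaluation with conservative win
    rules, classification-consistency metrics, and a synthetic fixture
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
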