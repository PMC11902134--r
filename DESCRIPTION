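Package: bmirecal
Title: Recalibration of BMI Cut-Offs for Adiposity Screening in Male Athletes
Version: 0.1.0
Authors@R:
    person("bmirecal", "developers", email = "devs@bmirecal.example.org",
           role = c("aut", "cre"))
Description: Tools to test and recalibrate body-mass-index (BMI) cut-off
    points for overweight and obesity against a body-fat-percentage (BF%)
    reference classification, as used in body-composition studies of athletic
    populations.  Provides a seeded synthetic athlete-cohort generator,
    adiposity classification under Gallagher BF% bands and arbitrary BMI
    cut-offs, agreement statistics (unweighted Cohen's kappa, uncorrected
    chi-squared, capture and false-positive rates, Landis-Koch labels), a
    residual-CUSUM linearity test with a Monte-Carlo permutation null,
    log-scale polynomial model building with back-transform prediction and
    validation (slope-of-one and paired t tests), and derivation of
    population-specific BMI cut-offs by substituting BF% thresholds into the
    fitted model.  A pipeline function reproduces the whole workflow on a
    cohort file and emits a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
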