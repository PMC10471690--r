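Package: synthq
Title: Cascaded Synthetic Data Generation for ME/CFS Questionnaire Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates statistically faithful synthetic patient-reported-outcome
    data for myalgic encephalomyelitis / chronic fatigue syndrome (ME/CFS)
    questionnaire batteries. Given real SF-36 item responses, a five-step
    cascade of per-question class-weighted classifiers produces synthetic
    HAD, SCL-90-R, FIS8, FIS40 and PSQI responses, with the cascade order
    derived from a thresholded Pearson correlation graph over questionnaire
    subscales. Includes subscale scoring for the six instruments, utility
    metrics for synthetic data (classification reports, signed mean error of
    questionnaire totals, sum-series t-tests), a seeded generator of
    correlated ordinal cohorts for offline testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
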