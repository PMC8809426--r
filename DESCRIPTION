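Package: facetrap
Title: Facial Photo-Identification Analysis for Camera-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Facetrap", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating facial photo-identification of unmarked
    carnivores (such as pumas) from camera-trap surveys. Builds independent
    detection events from timestamped photo records, classifies night/day by
    astronomical twilight, tests face-capture and behavioural contingency
    tables, measures multi-rater pairwise identity agreement with Fleiss'
    kappa and large-sample confidence intervals (including singleton
    adjustment and attribute-based pairing subsets), fits Poisson generalized
    linear mixed models of daily detection rates with backward model
    selection and type-III Wald tests, and simulates every input with known
    ground truth for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
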