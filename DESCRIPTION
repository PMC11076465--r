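Package: cogbattery
Title: Evaluation Pipeline for Remote Cognitive Test Batteries in
    Parkinson's Disease and Prodromal RBD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating unsupervised online cognitive test
    batteries in Parkinson's disease (PD) and REM sleep behaviour disorder
    (RBD) cohorts. Implements sociodemographic confound adjustment with
    rank-based inverse normal transformation, group and age-decade
    contrasts with standardized effect sizes, exploratory factor analysis
    with varimax rotation and one-factor global composites, a
    discriminability-versus-device task-selection procedure, convergence
    benchmarking against supervised screening scales (MoCA, MMSE), and
    cross-validated sensitivity analyses. Includes a latent-factor
    synthetic cohort generator with recorded ground truth for calibration
    and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    MASS,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
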