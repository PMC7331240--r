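Package: retest
Title: Test-Retest Reliability and Significant-Change Analysis for
    Standardized Behavioural Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies natural variability across repeated standardized
    behavioural assessments, such as robot-based (Kinarm) sensorimotor and
    cognitive test batteries. Implements the normalization and composite
    score transform stack (iterative Box-Cox de-skewing with outlier
    trimming, Zeta-scores, RSS and Mahalanobis distances, one-sided Task
    Scores with asymmetric confidence intervals), retest confidence
    intervals and significant-change thresholds from difference-score
    variability, consistency-type intraclass correlation, learning-effect
    testing with Benjamini-Hochberg false discovery rate control,
    trial-level intra-subject error, probabilistic impairment and change
    classification, and Monte Carlo sample-size simulation. A synthetic
    paired-assessment generator with known ground truth drives testing and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
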