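Package: tripleo
Title: Triple-O Connectome Outlier Detection for Early Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Abstracts a subject's whole-brain functional connectivity matrix
    into three global outlier measures against a normative reference cohort
    (count of outlying connections, mean Euclidean distance to the reference,
    and within-subject connection variability), Z-normalizes them and votes
    them two-of-three into a "brain outlier" call. A Cumulative Demographic
    Risk Index (gestational age at birth, birthweight, maternal education)
    optionally signs each call into a predicted high or low cognitive-outcome
    outlier. Includes cohort file I/O with the Fisher-Z transform,
    confusion-matrix evaluation with Fisher's exact test and CONTROL/RISK
    stratification, external-reference validation, reference-sample-size
    resampling with measure-stability curves, and a synthetic cohort
    generator with latent-trait connection coupling for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
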