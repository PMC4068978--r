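Package: castmove
Title: Quantifying Orthodontic Tooth Movement from Serial Dental Cast Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measurement pipeline for quantifying orthodontic tooth movement
    from serial three-dimensional dental cast scans. Superimposes pre- and
    post-treatment casts on untreated reference teeth via trimmed iterative
    closest point registration, registers each moved tooth rigidly, and
    decomposes the recovered transform into six clinical movement components
    (three translations in millimetres, three rotations in degrees) in a
    patient-specific arch coordinate system. Computes achieved-versus-planned
    treatment efficacy and the cohort summary statistics used in clinical
    aligner-efficacy studies (per-subgroup accuracy, splits by planned amount
    and staging, Shapiro-Wilk normality and paired t-tests). Includes a
    synthetic dental arch generator with known ground-truth movements and
    configurable scanner noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
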