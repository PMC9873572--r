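Package: lateralize
Title: Paired Accuracy Analysis of Lateralization Tests in Primary
    Aldosteronism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Within-patient comparison of two lateralization tests for
    primary aldosteronism: metomidate PET-CT and adrenal vein sampling.
    Implements deterministic grading of both investigations from raw
    measurements, PASO (primary aldosteronism surgical outcome)
    classification of post-adrenalectomy success, paired accuracy tables
    with Newcombe-Wilson score intervals, exact McNemar superiority and
    margin-based non-inferiority testing, sensitivity and false-positive
    rate estimation with Clopper-Pearson intervals, a stratified bootstrap
    sensitivity analysis for failed adrenal vein sampling, minimization
    allocation and discordant-pair power tools, predictor analyses
    (Oldham-corrected blood-pressure change, spironolactone response,
    immunohistochemistry H-scores), and a calibrated synthetic cohort
    generator for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
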