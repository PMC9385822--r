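Package: esnorms
Title: Equivalent Score Norms from Non-Parametric Tolerance Limits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds Equivalent Score (ES) norms for neuropsychological and
    other clinical test scores. Computes one-sided 95%/95% non-parametric
    tolerance-limit ranks (outer and inner) from the binomial distribution,
    subdivides the intermediate ES categories by ranks, z-scores, or direct
    trisection of the score scale, adjusts raw scores for demographic
    covariates by multiple regression, assigns ES categories (0-4) with an
    uncertainty flag for scores between the two tolerance limits, generates
    synthetic normative samples for method comparison, and tabulates
    reference ranks for arbitrary sample sizes. A command-line interface is
    provided for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
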