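Package: rihtool
Title: Scoring and Inter-Rater Reliability for the Responsible
    Innovation in Health Assessment Tool
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Responsible Innovation in Health (RIH)
    assessment instrument as a validated scoring engine: four dichotomous
    screening criteria, nine ordinal assessment attributes graded A-D on a
    non-equidistant 5/4/2/1 point scale, a three-level information-source
    quality hierarchy, and the rating step that combines them into an
    overall responsibility score with a four-interval verbal
    classification and a meaningfulness rule. Also provides the
    inter-rater reliability toolkit used to validate such instruments with
    two raters: weighted percent agreement, Gwet's AC1/AC2
    chance-corrected agreement coefficients with quadratic weights,
    linearized standard errors, confidence intervals and significance
    tests, Landis-Koch and Hinkle interpretation scales, Pearson
    correlation, and sample-size planning for agreement studies. A seeded
    synthetic two-rater generator with controllable marginals, agreement
    and missingness makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
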