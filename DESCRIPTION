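Package: immunoclock
Title: Immunological Aging Types, Reference Centiles and Equivalent Years of
    Life for Immune Age Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Age-conditional reference centiles for the immune age index
    IMMAX, a composite immunosenescence biomarker on the unit interval built
    by principal-component regression from five flow-cytometry blood-cell
    frequency ratios. Percentile curves are estimated by three algorithms
    (a location-scale-shape model on the logit scale, linear quantile
    regression, and penalized-spline nonparametric quantile regression),
    individuals are rated into six ordered immunological aging types, and
    agreement between rating algorithms is quantified with Krippendorff's
    alpha. Reference curves (model medians or a hypothetical progressive
    percentile profile) are inverted to rescale IMMAX into equivalent years
    of life (EYOL) and an immunological age gap, and longitudinal
    change-from-baseline analyses link EYOL and age-gap changes through the
    follow-up period length. A seeded synthetic-cohort generator with a
    known conditional quantile function supports parameter-recovery and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
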