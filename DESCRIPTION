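Package: radecol
Title: Radionuclide and Trace Element Distribution Analysis for Wildlife Tissue Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for radioecological tissue-distribution studies of
    wild mammals: radioactive decay correction and dry/wet mass-basis conversion,
    censoring-aware descriptive summaries, relative-to-muscle tissue distribution with
    paired sign-flip permutation inference, permutation correlation and
    difference-in-means tests, robust Bayesian correlation between radionuclides and
    their stable element analogues (bivariate Student-t likelihood sampled by adaptive
    random-walk Metropolis with split-Rhat and effective-sample-size diagnostics), and
    soil-to-whole-organism concentration ratios built from proxy tissues and
    moisture-derived conversion factors. Includes a seeded synthetic cohort generator
    emulating the correlation structure, heavy tails, outliers and below-detection
    censoring such studies exhibit, so the whole chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
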