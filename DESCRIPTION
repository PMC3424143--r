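Package: iapagree
Title: Agreement Between Central and Femoroiliac Venous Pressure Stratified
    by Intra-Abdominal Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Method-comparison toolkit for paired venous pressure
    measurements under varying intra-abdominal pressure (IAP). Estimates
    the one-way random-effects intraclass correlation coefficient (ICC)
    with an exact F-based confidence interval and Landis-Koch
    interpretation, scans IAP thresholds to profile subgroup concordance
    and select the best cutoff, tests the below/above-cutoff ICC
    difference by stratified bootstrap, fits a through-the-origin
    calibration regression, and computes ICC confidence-interval sample
    sizes for reliability study design. Includes a calibrated synthetic
    cohort generator with a changepoint bias model for paired pressures
    sharing a latent true value, plus CSV input/output and an
    end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
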