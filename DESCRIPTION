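Package: clusterbias
Title: Three-Level Factor Models and the Test for Cluster Bias
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Full-information maximum-likelihood estimation of two- and
    three-level confirmatory factor models on unbalanced nested data, and a
    global test of strong factorial invariance across the Level-2 and
    Level-3 clustering variables (the test for cluster bias). Includes
    chi-square fit statistics, RMSEA and CFI, chi-square difference tests
    with boundary caveats, latent and observed intraclass correlations,
    bias-proportion decompositions, per-indicator Wald tests of higher-level
    residual variances, and a three-level data simulator with type-I-error
    and power study harnesses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
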