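Package: stabsem
Title: Trait-Mediated Drivers of Community Temporal Stability via Piecewise
    Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking land-use intensity to the temporal stability of
    plant and arthropod communities through trait-based community features.
    Computes time-series community metrics (temporal stability as the inverse
    coefficient of variation, weighted species synchrony, weighted average
    population variability, mean richness and total abundance), trait-based
    features (community-weighted means, balanced Gower dissimilarity, Rao's Q
    functional diversity, PCA-derived dominant-trait axes), fits piecewise
    structural equation models with d-separation tests, Fisher's C and AICc,
    performs all-subsets term selection with an evidence-ratio rule, and
    decomposes fitted models into direct, indirect, total and mediator effects
    with bootstrap confidence intervals. Includes a synthetic multi-trophic
    landscape generator with known causal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    lmtest,
    car
Config/testthat/edition: 3
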