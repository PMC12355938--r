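Package: tprs
Title: Two-Phase and Multi-Phase Rejective Sampling for Design-Based Survey Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing two-phase (double) and three-phase
    samples with rejective (balanced) selection: a later-phase sample is accepted
    only when a Mahalanobis-type covariate balance statistic falls below a
    threshold. Implements simple random, Poisson, and stratified phase samplers
    with exact first- and second-order inclusion probabilities; double-expansion
    (pi-star), reweighted-expansion, and regression estimators of a finite
    population mean; the non-normal truncated-chi mixture limit law of the
    balanced component with Monte Carlo quantiles; design-consistent
    Horvitz-Thompson and Sen-Yates-Grundy variance estimators and confidence
    intervals; extensions to parameters defined by general estimating equations
    (proportions, variances, quantiles); exhaustive-enumeration oracles for tiny
    designs; and a Monte Carlo harness for design comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
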