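Package: featscreen
Title: Cross-Validated Feature Screening for Categorized Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts interpretable feature spaces from categorized images
    (Fourier magnitude bands, Fourier phase, histograms of oriented gradients,
    color value distributions, downscaled pixel intensities) and screens them
    for predictive value over category membership. Four feature selections
    (filter, wrapper, random, pseudorandom) are built per cross-validation
    fold and evaluated on holdout data; individual features are declared
    relevant through a label-permutation scheme whose control distribution
    corrects for regression to the mean. Includes a mock-data simulator with
    an exact whole-set null construction, t-test baseline selectors, a
    benchmark harness, report writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    png,
    jpeg,
    tiff,
    yaml,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
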