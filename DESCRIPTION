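Package: SpectralNB
Title: Wavelength-Optimized Naive Bayes Classification of Vis-NIR Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Gaussian naive Bayes discriminant analysis of visible and
    near-infrared absorbance spectra with two-stage wavelength-model
    optimization: exhaustive screening of equidistant wavelength
    combinations (initial wavelength, number of wavelengths, gap) followed
    by greedy step-by-step phase-out of individual wavelengths. Includes
    bottle-grouped calibration/prediction/validation splitting,
    recognition-accuracy metrics with a dispersion-penalized composite
    model-selection criterion, a synthetic Vis-NIR spectra generator with
    known informative bands and a bottle/sample/replicate hierarchy, and a
    reporting pipeline with an optional command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
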