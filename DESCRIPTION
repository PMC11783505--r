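Package: eventconn
Title: Event-Boundary fMRI Activation, Coactivation and Imaging-Genetics
    Modelling for Naturalistic Movie Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing region-of-interest (ROI) BOLD time series
    acquired during naturalistic movie watching. Implements simultaneous
    nuisance regression and discrete-cosine high-pass filtering, prewhitening
    with an eight-exponential autocovariance model, consensus event-boundary
    detection from observer annotations, boundary-locked univariate responses
    and PPI-style logistic coactivation, coactivation-based ROI merging,
    genotype-by-age linear models with Zellner-Siow Bayes factors for null
    evidence, permutation-tested linear-SVM genotype classification with
    balanced accuracy, and brain-network system segregation after global
    signal regression. A synthetic-data generator emulating a movie-watching
    cohort design (193 volumes, TR 2.47 s, ages 18-88, APOE genotype groups)
    makes the whole pipeline testable without access to managed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
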