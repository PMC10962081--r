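Package: loopstate
Title: Spatial Statistics for Chromatin-State Organisation Along Single
    Fibres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the organisation of histone
    modifications along single chromatin fibres imaged by single-molecule
    localisation microscopy (SMLM/STORM) and STED. Provides mean-shift
    clustering of localisation tables with FWHM cluster-width estimation,
    mutual-exclusivity statistics for two-colour data (overlap fractions
    relative to cluster centres and the cross-class mark connection
    function with a random-labelling Monte-Carlo envelope), 1-D intensity
    profile analyses (peak detection, inter-peak spacing, cross-channel
    lag via cross-correlation), k-nearest-neighbour association of marks
    with elongating RNA polymerase II, and a synthetic-data generator that
    emulates fibres built from chains of Gaussian nucleosome clusters so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
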