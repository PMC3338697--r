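Package: oligofluct
Title: Spatial Fluorescence Intensity Fluctuation Analysis of Membrane
    Protein Oligomerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers the surface density and quantal brightness (oligomeric
    state) of fluorescently labeled membrane proteins from single confocal
    microscopy images using two spatial fluctuation techniques: higher-order
    image moment analysis and spatial intensity distribution analysis (SpIDA),
    the fitting of super-Poissonian pixel-intensity histograms. Includes analog
    PMT shot-noise calibration and correction, normalization of brightness to
    monomeric equivalent units (MEU), a synthetic confocal image simulator with
    known ground truth for validation, and batch reporting with nonparametric
    group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
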