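Package: gatedflim
Title: Analysis of Wide-Field Time-Gated FLIM Plate Data for FRET Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing wide-field time-gated fluorescence lifetime
    imaging (FLIM) data from automated multiwell-plate microscopes. Provides
    calibration of the instrument response function (IRF profile, per-pixel
    shift map, global t0 from a reference dye), camera-background and
    time-varying-background correction, mono- and bi-exponential decay fitting
    with IRF convolution (pixel-wise, globally binned, and global fitting via
    separable nonlinear least squares), FRET donor population-fraction
    estimation, and plate-level screening statistics (well summaries, Z' factor,
    logistic dose-response IC50, biosensor time courses). A synthetic-data
    simulator emulates the instrument, producing time-gated plates with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
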