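Package: streaktrack
Title: Microsecond Single-Molecule Tracking from EM-CCD Streak Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of microsecond wide-field single-molecule
    tracking on electron-multiplying CCDs that stagger successive exposures
    along the chip by fast vertical charge shifts. Provides a synthetic-data
    generator for the acquisition (Brownian, tube-confined, and two-state FRET
    motion models; Gaussian PSF rendering under repeated exposure-shift cycles;
    EM-CCD Poisson-gamma noise), sub-pixel spot localization with theoretical
    precision estimates, greedy trail linking with skip placeholders and shift
    subtraction, variable-shift barcode design and Hamming-distance decoding to
    recover absolute positions, mean-squared-displacement diffusion analysis
    (linear and power-law fits, directional decomposition, spatial diffusion
    maps, super-resolution rendering), and two-state smFRET kinetics from
    time-correlated conditional probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
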