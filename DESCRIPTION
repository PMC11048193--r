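Package: pfec
Title: Pulse Feature-Enhanced Classification of Single-Particle
    Polarized Light Scattering Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying microalgae, cyanobacteria and other
    suspended particulate matter from single-particle polarized light
    scattering and fluorescence pulse trains. Covers the full pipeline:
    a synthetic instrument simulator (Poisson particle arrivals,
    bell-shaped transit pulses, species-dependent Stokes responses,
    channel noise, known instrument matrix), least-squares Stokes
    calibration of the 4x4 instrument matrix, pulse segmentation and
    conversion to calibrated Stokes-domain traces with degree of
    polarization, extraction of the 38-dimensional pulse-feature vector
    (or the 6-dimensional pulse-average baseline), a backpropagation
    neural-network classifier with stratified train/validation/test
    splitting and confusion-matrix evaluation, and sample-level
    composition reports with phylum renormalization, dominance labels
    and correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
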