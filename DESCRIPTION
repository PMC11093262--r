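Package: mweauc
Title: Simulation and Multiwavelength Analysis of Fluorescence-Detected
    Sedimentation Velocity Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and analysis of multiwavelength
    emission-detected analytical ultracentrifugation (MWE-AUC)
    experiments. Provides a finite-volume Lamm-equation solver for
    sedimentation-diffusion transport in sector-shaped cells, a model of
    the confocal fluorescence detector (excitation and collection spot
    geometry, grating dispersion, inner-filter attenuation, EMCCD shot
    and read noise with 16-bit digitisation), regularized c(s)
    distribution inversion with algebraic time- and radial-invariant
    noise elimination, assembly of two-dimensional
    sedimentation-coefficient versus emission-wavelength distributions
    with species-spectrum extraction and discrete-species global fits,
    and instrument quality-control computations (radial calibration,
    z-scan inner-filter assessment, signal-to-noise characterisation,
    dynamic range and radial resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
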