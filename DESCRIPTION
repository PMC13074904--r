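Package: srrtwin
Title: Digital-Twin Recovery of Optical Properties from Spatially
    Resolved Reflectance Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A Monte Carlo digital twin of a spatially resolved
    reflectance (SRR) imaging system for non-contact recovery of the
    absorption coefficient and the reduced scattering coefficient of
    turbid media.  Provides compiled photon-transport simulation of a
    homogeneous slab with an oblique, profile-weighted incident beam and
    Fresnel boundaries; perturbation Monte Carlo rescaling of stored
    photon paths for Jacobian assembly; a log-residual
    Levenberg-Marquardt inversion with common random numbers; the
    scaling-coefficient calibration that ties camera units to per-photon
    reflectance; a CCD image-preprocessing chain (flat-field correction,
    bloom detection and radial back-fill, multi-exposure stitching,
    radial binning); and a synthetic camera that renders physically
    plausible 16-bit frames so the entire pipeline can be exercised and
    validated without the instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow,
    withr
Config/testthat/edition: 3
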