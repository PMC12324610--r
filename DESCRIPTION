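Package: cfocus
Title: Compressive Fourier-Domain Intensity Correction for Two-Photon
    Microscopy Through Scattering Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes binary pupil-plane intensity masks that correct tissue
    scattering in point-scanning two-photon microscopy. Fluorescence signals
    recorded under random binary illumination patterns on a digital
    micromirror device (DMD) are inverted by an accelerated proximal-gradient
    solver (FISTA) with a total-variation regularizer; the recovered grayscale
    mask is binarized at a chosen output-to-input power ratio to keep the
    in-phase beams that interfere constructively at the target. The package
    also provides a physics-based virtual microscope (angular-spectrum
    propagation through random phase screens, quartic two-photon signal
    formation, point scanning with a finite memory effect), content-aware
    subregion segmentation for multi-patch correction, enhancement and
    point-spread-function metrology, effective-attenuation-length fitting,
    and plain-text serialization of patterns, masks, and measurement bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
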