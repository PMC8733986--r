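Package: txmdenoise
Title: Self-Supervised Denoising for X-Ray Nanotomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Self-supervised ("split-and-regress") denoising of low-dose
    parallel-beam X-ray nanotomography. A projection stack is split into two
    angle-interleaved halves, each half is reconstructed by filtered
    back-projection with a Shepp-Logan windowed ramp filter, and a mixed-scale
    dense convolutional network is trained to regress one half-reconstruction
    onto the other with early stopping on validation mean-squared error; the
    trained network denoises the half-reconstruction without clean reference
    data. Includes a transmission X-ray microscopy acquisition simulator
    (phantoms, Beer-Lambert attenuation, spatially varying illumination,
    Poisson plus Gaussian detector noise), a 3-D median baseline filter, and a
    quantitative evaluation layer (contrast-to-noise ratio, Gaussian full
    width at half maximum line-profile analysis, radial 1-D power spectral
    density, peak signal-to-noise ratio, difference-image statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
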