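Package: stripesim
Title: Structured Illumination Microscopy Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stripe-pattern structured illumination microscopy (SIM):
    binary stripe pattern generation for digital micromirror devices, a
    diffraction-limited optical model (OTF/PSF), a forward image-formation
    simulator with Poisson and read noise, raw-stack pre-processing
    (histogram matching, median filtering), estimation of illumination
    phases and frequency vectors from raw data (phase of peak, sub-pixel
    band correlation), and Fourier-domain band separation with generalized
    Wiener fusion producing a super-resolved image. Includes multi-page
    TIFF stack input/output, a YAML-configured pipeline runner and a
    swappable element-wise execution backend.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    parallel,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
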