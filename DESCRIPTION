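Package: forcepoint
Title: Contact-Point Detection in AFM Force Curves with 1D Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the contact point in atomic force microscopy (AFM)
    force-distance curves with one-dimensional convolutional neural networks.
    Provides a physics-based simulator of labeled approach curves (DLVO-type
    electrostatic double-layer plus van der Waals forces with jump-to-contact
    on hard charged surfaces; exponential steric repulsion with a compliant
    Hertzian contact regime and indentation events on soft films), a
    preprocessing pipeline (fixed-length resampling, min-max normalization,
    label encoding/decoding in physical units), two regression architectures
    (a three-block ConvNet-1D and a ResNet50-1D with bottleneck residual
    blocks) implemented natively with BLAS-backed convolutions and
    backpropagation, Adam training with best-epoch selection, classical
    threshold-based baseline locators, and evaluation of the signed
    contact-point error in nanometres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
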