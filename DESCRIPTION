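Package: cret
Title: Continuous-Representation Reconstruction for Fan-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fan-beam filtered back-projection (FBP) with a continuous-representation
    extension: the linear interpolation inside back-projection is augmented by a
    parameter-free sinusoidal-basis decoder fed by learned sinogram-domain features,
    so a region of interest can be reconstructed at arbitrary output resolution and
    detector binning scale. Includes sinogram squeezing/unfolding for memory-efficient
    region-of-interest reconstruction, a synthetic phantom and noise simulator, a small
    CPU-trainable convolutional encoder with an L1/Adam training loop, an optional
    image-domain restoration stage, and PSNR/SSIM evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
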