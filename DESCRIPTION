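Package: svimon
Title: Semantic Vegetation Index Monitoring from Repeat Photography
Version: 0.1.0
Authors@R: person("svimon", "Maintainers", email = "svimon@example.org",
    role = c("aut", "cre"))
Description: A semantic vegetation health monitoring toolkit for albums of
    repeat ground-level photographs. Registers repeat photographs of a site
    with a robust affine transform, segments vegetation pixel-wise with a
    small encoder-decoder (U-Net) network trained in-package, computes the
    Semantic Vegetation Index (SVI, the percentage of image pixels classified
    as vegetation) per image, and aggregates quarterly per-site SVI time
    series. Includes a synthetic repeat-photography scene generator with
    exact ground-truth masks and seasonal vegetation dynamics, a full
    segmentation evaluation kit (precision, recall, F1, overall accuracy,
    IoU/mIoU), paired image/mask augmentation, and an end-to-end pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
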