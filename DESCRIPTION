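Package: octlseg
Title: Label-Free Segmentation of Lymphatic and Aqueous-Vein Vessels in
    OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Optical coherence tomography lymphangiography (OCTL) segments
    optically transparent, low-backscatter vessels (lymphatics and aqueous
    veins) in 3-D OCT scans. The package implements the full pipeline:
    spectral-domain reconstruction of log-intensity volumes from raw
    interferograms, attenuation-coefficient fitting under the
    single-scattering model with confocal/roll-off system correction,
    attenuation-compensated constant-threshold vessel labelling, a
    from-scratch convolutional U-Net segmenter trained on those labels with
    Dice loss and Adam, agreement metrics (intersection over union, vessel
    area and volume densities) and en face projections. A synthetic speckle
    phantom generator with geometric vessel ground truth makes every stage
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
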