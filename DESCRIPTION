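Package: pbsr
Title: Histology-Guided Patch-Based Super-Resolution for Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs high-resolution ion images from low-resolution mass
    spectrometry imaging (MSI) acquisitions using a co-registered
    high-resolution histology image and a tissue segmentation as guides.
    Provides imzML reading and total-ion-count normalization, ion-image
    extraction, mutual-information similarity registration, the patch-based
    super-resolution algorithm itself (non-local reconstruction with
    segmentation constraints plus block-mean correction against the measured
    low-resolution image), an evaluation suite (SSIM, Welch's t-test,
    Cohen's d on ROI-versus-ring areas, intensity profiles, checkerboard
    composites, boxplot summaries), a seeded synthetic phantom generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
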