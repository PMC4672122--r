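Package: spinewave
Title: Dendritic Spine Detection and Classification in Fluorescence
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and classifies dendritic spines in 2D fluorescence
    microscopy images. The dendrite backbone is extracted by wavelet
    modulus-maxima contour detection followed by conditional symmetric
    pairing of opposite contour points; the dendrite boundary is located
    by marching from the backbone perpendicular to the local line
    direction until the intensity drops below a threshold. Spines are
    detected and classified into mushroom, stubby and thin morphologies
    by a regularized morphological shared-weight neural network (RMSNN)
    whose feature layers are learned gray-scale Hit-Miss transforms.
    Includes a seeded generator of synthetic confocal-like dendrite
    scenes and labeled spine subimage libraries with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
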