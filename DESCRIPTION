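Package: patchmoco
Title: Patchwise Motion and Distortion Correction for Two-Photon Calcium Imaging Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step registration of two-photon calcium imaging movies:
    rigid motion correction by pyramid-based hill climbing against
    iteratively re-estimated templates, followed by correction of slow
    non-uniform image distortions by patchwise affine transformations
    estimated through enhanced-correlation-coefficient (ECC) maximization
    on locally intensity-normalized mean images. Includes fully automated
    two-step across-session registration of summary images (Euclidean then
    patchwise affine, with automatic mean/max summary selection),
    registration-quality metrics (mean max-intensity difference and mean
    correlation with mean image), and a seeded synthetic-movie generator
    with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
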