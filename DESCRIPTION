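Package: pedistrip
Title: Skull-Stripping for Pediatric Brain MRI with Synthesis-Trained 3D U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Trains and applies 3D convolutional networks for brain extraction
    (skull-stripping) in pediatric head MRI without acquired training images.
    Whole-head label maps are built by splicing manual brain labels with
    Gaussian-mixture pseudo-labels fitted to the non-brain image content; at
    every optimization step a spatially augmented label map is rendered into a
    randomized synthetic head scan, the matching ground-truth brain mask and
    signed distance transform are derived morphologically, and a 3D U-Net is
    updated with a soft Dice or boundary-weighted distance loss. Includes a
    seeded head-phantom generator, conforming and resampling utilities, mask
    metrics (Dice, Hausdorff), and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    digest,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
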