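Package: taadmorph
Title: Morphometry and Segmentation Evaluation for Dissected-Aorta Label Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-segmentation analysis of type A aortic dissection from
    multi-label CT segmentations. Reads and writes NIfTI-1 label volumes
    (background, true lumen, false lumen), recovers the intimal flap by
    contour evolution over the merged lumen labels followed by region
    subtraction, quantifies per-slice and per-patient morphology (maximum
    Feret diameters, lumen areas, medial-axis flap thickness, relative
    errors), and evaluates predicted against reference segmentations with
    accuracy, precision, recall, IoU, Dice and the exact symmetric Hausdorff
    distance, together with cross-validation grouping and paired statistics.
    A synthetic dissection-phantom generator with analytically known
    morphometry supports validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
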