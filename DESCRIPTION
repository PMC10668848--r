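Package: openherd
Title: Open-Set Individual Identification from Livestock Face Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-set recognition for individual livestock identification from
    face images. Jointly trains a convolutional feature extractor with an
    additive-margin softmax (AM-Softmax) classification head and per-class
    reciprocal points under an adversarial margin constraint, so that known
    individuals are classified while novel (unknown) individuals are rejected
    by a distance-based known-ness score. Ships a procedural synthetic
    face-image generator emulating a herd with high inter-individual
    similarity and realistic nuisance variation (pose, illumination, fog,
    partial faces, occlusion, head size), the full known/unknown split and
    openness-ladder protocols, and threshold-free open-set metrics (AUROC,
    OSCR, closed-set accuracy, macro F1, openness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
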