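Package: texgrade
Title: Texture-Based Malignancy Grading of Tissue-Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pattern-classification pipeline for grading breast-cancer
    tissue-section images captured at low magnification (x10). Computes 30
    texture descriptors per 512x512 region of interest (4 first-order
    statistics, 16 gray-level co-occurrence descriptors, 10 run-length
    descriptors), reduces them with a per-feature analysis-of-variance
    significance filter, finds the best feature combination by exhaustive
    search scored with leave-one-out accuracy, classifies regions into
    histological grades I-III with k-nearest-neighbour, probabilistic
    neural network (Parzen kernel) or support-vector-machine back ends,
    and estimates generalization accuracy with repeated stratified
    external cross-validation. Includes a seeded synthetic texture
    generator that emulates the three grade morphologies so the whole
    pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    class,
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
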