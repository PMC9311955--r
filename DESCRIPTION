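Package: mpsuture
Title: Midpalatal Suture CBCT Fusion, Texture Analysis and Age-Range Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of the midpalatal suture in
    cone-beam computed tomography (CBCT). Extracts the normalized 50x200
    suture region of interest from labeled axial slices, fuses the
    multi-slice stack into a single contrast-enhanced image by pairwise
    weighted merging with optional Laplacian sharpening, computes
    gray-level co-occurrence matrix (GLCM) texture features and their
    relationship with chronological age, trains a residual convolutional
    network to classify five age ranges, explains predictions with
    Grad-CAM heat maps, and evaluates classifiers with per-class
    precision/recall/F1 and one-vs-rest ROC/AUC. A seeded synthetic
    phantom generator emulates the structure of a clinical CBCT database
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
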