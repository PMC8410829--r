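Package: CryoMetSeg
Title: Metastasis Segmentation and Quantification in Whole-Mouse Cryo-Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection, segmentation, classification and burden quantification
    of fluorescent-protein-labeled metastases in whole-mouse cryo-imaging
    volumes (co-registered RGB anatomy and green-fluorescence channels).
    Candidate generation combines marker-controlled 3D watershed segmentation
    of large bright tumors on down-sampled volumes with chunked multi-scale
    Laplacian-of-Gaussian detection of small metastases at full resolution.
    Candidates are classified by a random forest on multi-scale 3D
    convolutional network features plus hand-crafted location, intensity and
    morphology features, or by fusing the per-scale network probabilities.
    Includes a seeded synthetic whole-mouse phantom generator with known
    truth labels, score-based evaluation (ROC/PRC, false positives at target
    sensitivity, mouse-level cross validation), programmatic correction of
    classification results, and tumor-burden reports with an exponential
    growth model for cell counts and doubling times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    ranger,
    tiff,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
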