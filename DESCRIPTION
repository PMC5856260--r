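Package: fibroquant
Title: Automated Histomorphometry of Lung Fibrosis on Trichrome Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("fibroquant", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated two-stage quantification of pulmonary fibrosis on
    Masson's trichrome stained whole-slide images. A low-magnification support
    vector machine (SVM) tissue classifier segments background, fibrotic masses,
    alveolar tissue and bronchi, yielding an exclusion map, the alveolar region
    of interest and the percent area of fibrotic masses. A high-magnification SVM
    collagen classifier, applied tile-wise (512x512, map-reduce) inside the
    alveolar region of interest, yields percent alveolar collagen and percent
    total collagen. Includes a synthetic trichrome slide generator with exact
    ground truth for end-to-end testing without scanned slides, stratified k-fold
    cross-validation, batch processing and Mann-Whitney group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
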