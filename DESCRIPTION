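Package: dihm
Title: Digital In-Line Holographic Microscopy Pipeline for Plankton Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested end-to-end workflow for point-source (Gabor) digital
    in-line holographic microscopy of plankton: a forward simulator for
    synthetic holograms with known ground truth, angular-spectrum wavefield
    reconstruction of a z-stack through the sample volume under the Fresnel
    scaling theorem, Otsu-based detection of regions of interest with a
    physical size gate, DBSCAN grouping of detections across focal planes
    with Vollath F4 autofocus selection, a dataset builder (128x128
    standardization, threefold flip/translate augmentation, 50:10:40 split,
    stratified k-folds, noise class), a compact pluggable convolutional
    classifier trained with Adam under a reduce-on-plateau schedule, and
    threshold, probabilistic and ranked evaluation (one-vs-all
    precision-recall curves, average precision, class baselines,
    fold-ensemble statistics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
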