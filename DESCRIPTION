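Package: histoseg
Title: Nucleus Instance Segmentation and Whole-Slide Classification for
    H&E Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two common tasks in digital pathology image
    analysis. The segmentation half implements an encoder-decoder deep
    residual aggregation network (single-scale and multiscale) with
    valid convolutions for nucleus blob and boundary prediction,
    followed by dilation/subtraction, marker-controlled watershed
    separation of touching nuclei, and a physical-area artifact filter;
    instance agreement is scored with the pixel Dice coefficient and an
    object-level Ensemble Dice that penalizes splits and merges. The
    classification half stain-normalizes tissue patches (Reinhard color
    transfer), classifies them with a 32-layer residual network into
    lung adenocarcinoma, squamous cell carcinoma, or non-diagnostic
    tissue, assembles per-slide class probability maps, extracts 50
    statistical and morphological map features, and classifies slides
    by max voting or a bagged regression forest. A synthetic-data
    module generates H&E-like tiles with exact labeled masks and
    class-conditional patch grids so the full pipeline is testable
    without any slide data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    randomForest
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'histoseg-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'engine.R'
    'seg_net.R'
    'cls_patches.R'
    'fixtures.R'
    'io.R'
    'metrics.R'
    'seg_data.R'
    'seg_pipeline.R'
    'wsi_agg.R'
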