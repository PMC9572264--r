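Package: periseg
Title: Periodontal Ultrasound Annotation, 3D Quality Control and U-Net Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for multi-class segmentation of periodontal
    ultrasound frames. Provides a synthetic sweep phantom (frames, per-class
    masks, probe poses, controlled label corruption), a seeded region-growing
    annotation engine with a replayable session state machine, dataset
    preparation into the 384x384x5 training representation with reproducible
    train/validation/test splits, freehand-3D compounding of posed frames into
    intensity/label volumes with a neighbour-consistency quality check for
    annotation errors, a configurable U-Net (built, trained and applied in
    native code, no external deep-learning framework), and instance/pixel
    evaluation metrics (presence confusion, true-positive-restricted IoU,
    weighted average IoU, size/prevalence correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    png,
    yaml,
    jsonlite,
    RNifti,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
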