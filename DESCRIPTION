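Package: readercad
Title: Reader-Study Evaluation of Lesion-Detection CAD on Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-reader multi-case (MRMC) evaluation of
    computer-assisted detection (CAD) of lung nodules on chest radiographs.
    Implements bounding-box intersection-over-union (IoU) matching with an
    inclusive 0.3 correctness threshold, case-level TP/FN/TN/FP
    classification, mean false-positive indications per image (mFPI),
    sensitivity/specificity/accuracy/PPV/NPV panels with pre/post-CAD
    ratios, per-reader decision-transition tables conditioned on CAD
    correctness, and generalized estimating equations (log link, sandwich
    variance) for with-CAD versus without-CAD performance ratios on
    reader-clustered binary outcomes. A calibrated synthetic reader-study
    generator reproduces the statistical structure of a chest-radiograph
    nodule-detection reader study so the full pipeline runs without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
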