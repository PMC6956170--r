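Package: lsasvm
Title: Self-Advised and Label Self-Advised Support Vector Machines for
    Myoelectric Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Support vector machine post-processing for biomedical signal
    classification. Implements the self-advised SVM (SA-SVM), which mines
    the misclassified training set for per-point neighborhood radii and
    uses them to override low-confidence test predictions, and its
    label-space variant (LSA-SVM), where neighborhood lengths and advised
    weights are computed on encoded class labels instead of feature
    vectors. Ships the full offline surface-EMG pattern-recognition
    pipeline around the classifiers: band-pass and mains-notch filtering,
    polyphase resampling, sliding-window segmentation, time-domain feature
    extraction (MAV, RMS, waveform length, zero crossings, slope-sign
    changes, and friends), stratified cross-validated benchmarking of
    c-/nu-SVM and their advised variants, synthetic data generators for
    every stage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
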