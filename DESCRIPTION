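Package: dwtselect
Title: Optimal Discrete Wavelet Transform Settings for EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Searches the settings of the discrete wavelet transform (DWT)
    that maximize cross-validated seizure/non-seizure classification accuracy
    of EEG segments at minimal feature dimension. Provides a catalog of 54
    mother wavelets across 7 families, multilevel Mallat filter-bank
    decomposition with band-to-frequency mapping onto conventional EEG
    rhythms, nine per-band coefficient statistics, and two exhaustive search
    procedures: Wavelet-Level Selection (best mother wavelet and decomposition
    level per family) and Band-Feature Selection (best subsets of frequency
    bands and features). Includes EDF and plain-text EEG readers, windowed
    segmentation with seizure-interval labeling, FIR high-pass preprocessing,
    subject-aware class balancing, an RBF-kernel SVM evaluation harness with
    leave-one-subject-out and stratified k-fold cross-validation, and a
    multi-subject synthetic EEG generator with controlled rhythm-band effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
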