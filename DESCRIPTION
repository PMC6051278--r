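Package: jwavesst
Title: J-Wave Detection in ECG via Synchrosqueezed Wavelet Transform and
    Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for automatic detection of the J wave, a
    bump on the descending slope of the terminal QRS complex of the
    electrocardiogram that is associated with malignant arrhythmia.
    Provides a synthetic single-lead ECG generator with controllable
    J-wave morphology, Daubechies-6 wavelet denoising, Pan-Tompkins
    R-peak detection and beat segmentation, the synchrosqueezed
    continuous wavelet transform (SST) with ridge extraction and
    inverse-SST reconstruction of intrinsic modes, time-frequency and
    mode-entropy features (Renyi, approximate and sample entropy), and a
    random-forest classifier with sensitivity, specificity, MCC and AUC
    reporting and per-feature Welch t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
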