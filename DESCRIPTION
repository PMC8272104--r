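Package: bitecg
Title: Time-Morphology Electrocardiomatrix Representations and a
    Beat-Interval-Texture CNN for Short Single-Lead ECGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms short, variable-length single-lead
    electrocardiogram (ECG) recordings into fixed-size 180x240
    consistent-sized electrocardiomatrix (CS-ECM) images and classifies
    them into normal sinus rhythm, atrial fibrillation, other arrhythmia
    and noisy classes with a beat-interval-texture convolutional neural
    network (BIT-CNN).  Includes a Pan-Tompkins style R-peak detector, a
    seeded synthetic ECG generator for the four rhythm classes,
    stratified cross-validation with class-rebalancing resampling,
    confusion-matrix scoring (per-class F1 and the NAO/NAOP macro
    averages), and visual interpretability tools (per-block and
    filter-type Grad-CAM, PCA plus t-SNE embedding maps).  The network,
    its back-propagation training and the attention modules are
    implemented in compiled code with no external deep-learning
    framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    png,
    Rtsne,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
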