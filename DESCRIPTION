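Package: drowse
Title: Driver Fatigue Identification from Facial Landmark Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies driver fatigue from per-frame facial landmark
    coordinates. Computes geometric eye and mouth opening features (aspect
    vectors, opening angles, closure-area ratios) and head-pose Euler angles
    from five-point correspondences, denoises the feature series with an
    FFT-based zero-phase smoother, reduces the eleven features to common
    factors by principal-component factor analysis with varimax rotation, and
    classifies sliding windows of factor scores with a generalized regression
    neural network (GRNN) whose smoothing factor is tuned by a real-coded
    genetic algorithm minimizing leave-one-out mean squared error. Ships a
    synthetic landmark-stream simulator with state-dependent blink, yawn,
    speech and head-nod events so the full pipeline is testable without video
    data, plus an improved IoU-family bounding-box regression loss and
    non-maximum suppression as standalone geometry utilities, and
    confusion-matrix evaluation with repeated stratified cross-validation
    against k-nearest-neighbour and random-forest baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
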