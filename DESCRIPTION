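Package: gaitstride
Title: Stride-Length Estimation from Foot-Worn IMU Signals with a
    Quantizable 1D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for estimating gait stride length (cm)
    from a foot-mounted six-axis inertial measurement unit. Provides a
    synthetic treadmill-gait signal generator with known ground truth,
    readers and writers for the TRIPOD-style CSV layout and a JSON
    labelled-stride exchange format, signal pre-processing (sensor-range
    normalisation, 60 Hz resampling, zero-phase Butterworth filtering,
    gyroscope-based initial-contact detection, stride segmentation and
    zero padding), a from-scratch 1D convolutional regression network
    trained with Adam, post-training int8 quantization with a reference
    integer inference engine and C-array exporter, and Bland-Altman
    agreement statistics with leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
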