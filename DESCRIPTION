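Package: imuqc
Title: Autonomous Quality Control of IMU-Derived Joint Orientation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to assess the quality of joint-orientation estimates obtained
    from body-worn inertial measurement units (IMUs) without access to a gold
    standard at measurement time. Segments of attitude-and-heading reference
    system (AHRS) output are classified as acceptable or not by a small
    feedforward neural network fed with sixteen features computed from the raw
    accelerometer, gyroscope and magnetometer signals of the two modules
    spanning a joint. Includes quaternion orientation algebra, resampling and
    cross-correlation synchronization of sensor streams, segment feature
    extraction and normalization, class-balanced regularized network training,
    sensitivity/specificity evaluation, and a synthetic timed-up-and-go cohort
    generator with configurable magnetic-disturbance and velocity-driven
    orientation-error models so the whole pipeline can be exercised end to end
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
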