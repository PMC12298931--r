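Package: gaitaccel
Title: Acceleration Decomposition for Shank-Mounted Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Gait analysis from 9-axis inertial measurement units worn on the
    lower leg. Estimates sensor orientation (roll, pitch, yaw) by fusing
    gyroscope, accelerometer and magnetometer data with an extended Kalman
    filter whose process and observation noise covariances adapt to the sensor
    output and whose tuning coefficients are selected by maximising the
    innovation log-likelihood. The accelerometer signal is then decomposed
    into gravitational, centrifugal, tangential and translational components,
    and the components are summarised over time-normalised gait cycles. A
    synthetic gait simulator with closed-form kinematics provides exact ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
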