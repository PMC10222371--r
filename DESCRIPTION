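Package: standcom
Title: Center-of-Mass Estimation for Standing Balance from Force-Platform
    and Head-IMU Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the horizontal displacement, velocity and acceleration
    of the whole-body center of mass (COM) during quiet standing and
    perturbed stance from force-platform signals, optionally fused with a
    head-mounted inertial measurement unit. Implements algebraic inversions
    of linearized single- and double-inverted-pendulum models of upright
    posture in the sagittal and frontal planes, a constant-velocity Kalman
    filter that fuses moment-derived COM displacement with force-derived COM
    acceleration, and two classical baselines (low-pass filtering of the
    center of pressure, and drift-stabilized double integration of COM
    acceleration). A synthetic trial generator with matched linear inverse
    dynamics and an independent nonlinear Newton-Euler oracle provides
    ground truth for validating every estimator, together with windowed
    RMSE/correlation metrics and a COP-correlation applicability test for
    the force-plate-only method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
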