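Package: wheelsprint
Title: IMU-Based Kinematics, Force-Velocity Profiling and Symmetry
    Analysis of Repeated Wheelchair Sprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for repeated 20 m manual-wheelchair sprint
    tests recorded with wheel-, frame- and trunk-mounted inertial
    measurement units (IMUs). Converts wheel gyroscope signals to
    camber-corrected linear velocity, detects sprint boundaries and
    propulsion cycles, fits a 4th-degree velocity polynomial to derive
    propulsive force and power (with rolling resistance estimated from
    coast-down trials and an aerodynamic drag term), computes the
    Instantaneous Symmetry Index over start/middle/end cycle windows,
    and derives trunk range of motion from quaternion orientation via a
    y-z-x Euler sequence. Includes a synthetic-session generator with
    known ground truth for validation, and a group report stage with
    normality-routed comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
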