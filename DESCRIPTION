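Package: comtransfer
Title: Frontal-Plane Center-of-Mass Transfer Analysis for Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Projects the frontal-plane center-of-mass (CoM) transfer
    magnitude of a walking step from the instantaneous mediolateral CoM
    position and velocity using closed-form linear inverted pendulum
    (LIPM) dynamics, and builds a complete gait-analysis pipeline on top
    of that projection: zero-phase Butterworth filtering of kinematic and
    kinetic streams, force-based gait event detection (initial contact,
    contralateral foot off, transfer completion), per-step metrics
    (foot placement, velocity, projected and final transfer magnitudes,
    trailing-limb mechanical work during double support), and
    participant-level summaries of transfer asymmetry, phase
    contributions, prediction error, step-to-step control and
    variability. A synthetic treadmill-trial generator with exact
    analytic ground truth makes every stage testable without motion
    capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
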