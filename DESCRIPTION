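Package: limbphase
Title: Phase Shift Between Joint Actuation and Motion Across Scales of
    Legged Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models a one-segment limb as a hanging pendulum (swing) and an
    inverted pendulum carrying the body (stance) with viscoelastic joint
    properties obtained from allometric scaling laws.  Computes the phase
    shift between actuator moment and joint angle as a function of limb
    length and cycle period, classifies dominant-force regimes (kinetic,
    quasi-static, viscous), generates work loops with per-cycle energy
    partitions, forward-simulates perturbation responses and passive stance
    stability, and predicts protractor/retractor muscle activation envelopes
    for walking animals from horse to stick-insect scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
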