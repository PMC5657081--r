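Package: torsionrig
Title: Cyclic Torsion Analysis for Physeal Fracture Fixation Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cyclic torsional load-displacement data from
    ex vivo bone-implant constructs, with a focus on Kirschner-wire fixation of
    Salter-Harris type I physeal fractures. Provides a synthetic test-rig
    simulator (sinusoidal torque protocol, sigmoidal torque-angle backbone with
    an interfragmentary toggle region, retro-reflective marker trajectories
    with actuator-bone slippage), per-cycle gross angular displacement,
    terminal-slope torsional stiffness via an iterative R-squared-thresholded
    regression, toggle estimation from terminal-line x-intercepts, marker
    rotation angles via projection and the Law of Cosines, and linear
    mixed-effects group comparisons across one-, two- and three-pin fixation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
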