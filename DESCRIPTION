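Package: mfresponse
Title: Simulation and Kinematic Analysis of Manual Following Responses in
    an Interception Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing an interception experiment in
    which a briefly moving square near the movement endpoint pulls the hand in
    the direction of the square's motion (the manual following response).
    Provides the task paradigm (geometry, randomized trial schedules, stimulus
    kinematics), a 500-Hz synthetic marker-trajectory generator with a
    controllable injected following response, low-level kinematics (four-point
    screen calibration, direct velocity differentiation, tap detection and hit
    classification), and the response analysis (trial exclusion,
    direction-difference velocity time courses, window-mean response
    magnitudes, and group summaries with standard errors across participants).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
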