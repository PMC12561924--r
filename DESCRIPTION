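Package: spheregaze
Title: Spherical Gaze Analysis for Eye, Head, and Torso Coordination in 360-Degree Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visual exploration of 360-degree panoramic
    environments from multi-rate eye, head, torso, and chair orientation
    streams. Fuses eye-in-head direction vectors with head orientation
    quaternions into gaze positions on the unit view-sphere, detects
    fixations with a spherical dispersion-threshold algorithm, quantifies
    scene exploration (gaze travel distance and overlap-corrected spherical
    cap coverage), characterises longitude and latitude distributions of
    every effector frame, estimates eye-head-torso coordination dynamics
    (eyes-in-head eccentricity locked to saccade onsets, head-to-torso
    rotation onset delays), and runs the repeated-measures group statistics
    used to compare posture conditions. Includes a posture-conditioned
    synthetic generator of orientation streams so the full pipeline can be
    exercised and calibrated without access to raw study recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
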