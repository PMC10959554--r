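Package: turngait
Title: Spatiotemporal Analysis of Turning Gait with Bayesian Equivalence Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how walking speed and turning amplitude shape
    the spatiotemporal gait pattern during walk-turn-walk trials. Generates
    synthetic marker trajectories (heel, toe and pelvis markers at 120 Hz)
    with exact ground truth, detects heel-strike and toe-off events from
    marker kinematics in a pelvis-local progression frame, segments the
    turning period from pelvis yaw rate (30 deg/s rule), extracts whole-turn
    and per-leg parameters (speed, duration, steps, cadence, stride/step
    length, signed stride width, cycle/stance/double-support times),
    aggregates trials to per-subject means and within-subject variability,
    and performs Bayesian repeated-measures inference with highest-density
    intervals, region-of-practical-equivalence decisions, Savage-Dickey
    Bayes factors and MCMC diagnostics. Reads and writes TRC and CSV marker
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
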