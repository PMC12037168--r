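Package: joykin
Title: Simulation and Kinematic Analysis of Head-Fixed Mouse Joystick Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing head-fixed mouse joystick
    behavior. Implements the two task engines of an open-source joystick
    platform (an auditory-motor two-alternative forced-choice task and a
    two-armed bandit value task with un-cued probabilistic reversals), the
    joystick signal-processing chain (ADC calibration, moving-average
    smoothing, re-baselining, threshold choice detection), a trajectory
    kinematics suite (tortuosity, discrete Frechet distance, movement
    velocity, explored-area occupancy grids, circular angular deviation),
    velocity-based movement-bout segmentation with per-trial vigor readouts,
    and a two-parameter forgetting Q-learning model with maximum-likelihood
    fitting, uncertainty splits, win-stay/lose-switch and choice-history
    regression summaries. Ships virtual agents and synthetic trajectory
    generators so every analysis can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
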