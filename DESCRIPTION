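Package: ethokinetics
Title: Trajectory Kinematics for Rodent Open-Field and Sociability Assays
Version: 0.1.0
Authors@R:
    person("Eve", "Kinney", email = "ekinney@example.org", role = c("aut", "cre"))
Description: Centroid tracking of a single dark animal in grayscale video
    frame stacks, calibration to arena coordinates, and bespoke trajectory
    kinematics for rodent behavioral tests: traveled distance, effective
    velocity (immobile time excluded), mean acceleration (positive
    frame-to-frame velocity increments), stop counts and distance per stop;
    minute-by-minute habituation profiles; zone partitioning and occupancy
    for the open field, three-chamber sociability apparatus and elevated
    plus maze, including social/non-social kinematic ratios; nonparametric
    and mixed-ANOVA group comparisons; and a seeded correlated-random-walk
    simulator plus blob-video renderer providing ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
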