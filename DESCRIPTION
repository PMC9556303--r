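Package: exoloop
Title: Human-in-the-Loop Optimization of Ankle Exoskeleton Assistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven human-in-the-loop optimization of ankle exoskeleton
    assistance. Implements the four-parameter torque control law, gait-cycle
    segmentation and feature binning, a lasso-regularized pairwise preference
    classifier that ranks control laws from kinematics alone, a CMA-ES
    generation loop, speed-adaptive control interpolating per-speed optima from
    stride period, opportunistic real-world optimization over naturalistic
    walking bouts with speed bins, indirect-calorimetry energetics, and a
    simulated participant with a ground-truth metabolic landscape for
    end-to-end desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
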