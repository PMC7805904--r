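Package: gaitbench
Title: Benchmarking Gait Stability from Whole-Body Dynamics Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking the stability of bipedal walking from
    marker-based motion capture. Builds subject-specific rigid multibody models
    from anthropometric regression tables, converts marker trajectories into
    generalized-coordinate reference motions by whole-chain least-squares
    inverse kinematics, reconstructs dynamically consistent states and joint
    torques with a multi-phase least-squares optimal control problem over the
    gait-cycle contact schedule (rigid contacts and perfectly inelastic
    impacts), and computes stability benchmarks: the Instantaneous Capture
    Point, the normalized orbital energy of the linear inverted pendulum, the
    Residual Orbital Energy at heel strike, and the decomposition of whole-body
    angular momentum into upper- and lower-body contributions. Includes a
    synthetic gait generator (closed-form linear-inverted-pendulum walking and
    forward-simulated multibody strides with marker synthesis) so the entire
    pipeline can be exercised without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
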