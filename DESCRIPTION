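Package: wristexo
Title: Biomechanical Models for Wrist-Rehabilitation Exoskeletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational models for distal-radius-fracture wrist
    rehabilitation with wearable exoskeletons: friction statics of the
    reduced fracture end under external fixation, a planar Lagrangian
    model of spring-resisted wrist rotation, modified Denavit-Hartenberg
    forward kinematics of a four-kit rope-spring resistance device with
    per-pattern resistance forces, hysteresis repetition counting and
    range-of-motion extraction from joint-angle traces, and a surface-EMG
    pipeline (orthogonal wavelet denoising with db4 and integrated-EMG
    muscle-activation indices). Synthetic generators for joint-angle and
    burst-structured sEMG signals make every stage testable without
    recorded human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
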