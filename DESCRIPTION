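Package: gaitresilience
Title: Resilience of Locomotor Behavior to Rhythmic Auditory Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the resilience of treadmill walking to temporal
    perturbations of an auditory metronome. Detects gait events from foot
    marker kinematics, builds subject-specific metronome tracks with
    beat-delay perturbations, reconstructs sacral (centre-of-mass) vertical
    displacement in state space by time-delay embedding, fits a torus-shaped
    steady-state boundary (reference trajectory plus per-degree 1/2/3 sigma
    ellipses) from baseline walking, parameterises the perturbation response
    of the deviation series (lag time, peak time, peak magnitude, recovery
    time), quantifies footfall-beat asynchrony and its recovery, and provides
    group-level estimation statistics. Includes a synthetic gait generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
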