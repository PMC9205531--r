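Package: activereach
Title: Active Inference Simulation of One-Degree-of-Freedom Arm Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates goal-directed reaching and conflict-resolution movements
    of a one-degree-of-freedom arm (elbow rotation) with an active inference
    agent that minimizes Laplace-approximated variational free energy through
    coupled perceptual inference and action. The generative process is a damped
    arm with sublinear velocity damping observed through noisy proprioceptive
    (joint angle) and visual (Cartesian hand position) channels; the agent's
    generative model tracks the arm in generalized coordinates up to second
    order and embeds goals as a point attractor in its internal dynamics.
    Includes scenario builders for visually guided reaching, the rubber hand
    illusion (a static misplaced fake hand), and reaching while embodying a
    velocity-gained virtual arm, plus trajectory metrics (settling time,
    proprioceptive drift, inferred-velocity dissociation, action-component
    cancellation), config/trajectory serialization, figure builders, and a
    command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
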