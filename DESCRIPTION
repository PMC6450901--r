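Package: popcoupling
Title: Population Coupling and Body-Movement Coupling of Motor Cortex Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking each recorded neuron's coupling to the
    population (spike-count covariation with the summed activity of the other
    units) with its coupling to body movement, for spike trains recorded
    together with 3D motion-capture bead trajectories. Implements
    movement-triggered and spike-triggered average waveforms with circular-shift
    surrogate nulls, a permutation test for non-monotonic (peaked)
    relationships, a per-session quadratic-fit consistency test, a binary
    probabilistic network model with activity-dependent adaptation, and a
    synthetic-session generator with known ground-truth coupling structure so
    every stage runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
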