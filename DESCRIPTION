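Package: stimbandit
Title: Closed-Loop Bandit Optimization of Brain-Stimulation Sites via
    Behavioral State-Space Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation testbed for optimizing which deep-brain-stimulation
    contact to activate, using reaction times from a cognitive-conflict task
    as the feedback signal. Provides a latent-state generator of
    gamma-distributed reaction times with AR(1) cognitive-state dynamics, an
    online state-space "sensor" fitted by expectation-maximization with
    Kalman-type filtering, a suite of multi-armed-bandit site-selection
    algorithms (greedy, epsilon-greedy, UCB1, Bayes-UCB, Thompson-sampling
    variants, brute force) run block-wise in closed loop, and an experiment
    harness that sweeps blocksize, trial budget, problem size,
    signal-to-noise ratio, effect discriminability and ensemble voting to
    measure each optimizer's probability of identifying the globally best
    stimulation site.
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
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
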