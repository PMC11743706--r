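Package: plantarstiff
Title: Interpretable Plantar Soft-Tissue Stiffness Modelling from Regional
    Plantar Pressure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts plantar soft-tissue stiffness (N/m) from the mean
    plantar pressure of ten foot regions recorded during the stance phase
    of walking.  A three-layer backpropagation regression network (10-13-1)
    is initialized by a hybrid particle-swarm / genetic-algorithm optimizer
    in which, every swarm iteration, the best genetic-algorithm individual
    replaces the worst particle.  The fitted network is evaluated with mean
    bias error, root mean square error and relative error percentage, and
    interpreted by Mean Impact Value (MIV) feature attribution with
    normalized per-region contribution rates.  Includes a seeded synthetic
    gait-cohort generator (regional pressures, stance-phase time series and
    damped-oscillation stiffness traces) so the full pipeline is testable
    without access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
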