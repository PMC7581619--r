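Package: biogasMPC
Title: Model-Based Biogas Production Management for Anaerobic Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for demand-driven operation of anaerobic digesters: a
    nonlinear Monod-Haldane kinetic model of bacterial growth, substrate
    decomposition and biogas generation with an RK4 simulator; Jacobian
    linearization and exact zero-order-hold discretization; an adaptive
    parameter-estimation system (filtered regressors, batch and recursive
    least squares with a substrate-input switch); minimal state-space
    realization from identified input-output models via block-Hankel
    factorization (Ho-Kalman); an unconstrained model-predictive feedstock
    controller with receding-horizon simulation and integration of the
    optimal input into feasible discrete feeding events; goodness-of-fit
    and tracking metrics; and a synthetic operation-data workbench that
    emulates hourly reactor records for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
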