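Package: pivpressure
Title: Pressure Field Reconstruction from 2D Velocimetry Around Swimming Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the instantaneous two-dimensional pressure field --
    including the pressure on a moving, deforming body surface -- from
    time-resolved 2D velocity-field measurements such as particle image
    velocimetry (PIV) around swimming fish. The core method trains a
    physics-informed neural network (a coordinate network whose outputs are
    constrained by the Navier-Stokes momentum residuals, the measured
    velocities, and boundary conditions including a non-penetration condition
    on the undulating body) so that its pressure output can be evaluated
    anywhere, in particular exactly on the body contour. Classical baselines
    (a pressure-Poisson solver and multi-directional pressure-gradient
    integration with nearest-node surface extrapolation) and an analytic
    synthetic-flow subsystem (Taylor-Green vortex, unsteady potential-flow
    swimmer surrogate with prescribed carangiform kinematics) make every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    yaml
Config/testthat/edition: 3
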