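Package: oscgrain
Title: Data-Driven Coarse-Graining of Coupled Phase Oscillator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering coarse variables, coarse evolution
    equations, and reduced "effective" parameters for networks of coupled
    phase oscillators. Simulates Kuramoto-family models (all-to-all,
    heterogeneous coupling, excitable "firing" variant, and Chung-Lu random
    networks), identifies coarse variables from phase-density snapshots via
    diffusion maps with local-linear-regression eigenfunction selection,
    extends functions off the sampled manifold with geometric harmonics,
    and learns ordinary differential equation right-hand-sides from flow
    pairs with a feedforward network templated on a fourth-order
    Runge-Kutta integrator. Results are validated against the analytic
    Ott-Antonsen reduction of the all-to-all Kuramoto model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
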