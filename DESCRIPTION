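Package: invaertcv
Title: Amortized Inversion and Stiffness Analysis for the CVSim-6 Haemodynamic Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Six-compartment lumped-parameter (CVSim-6) cardiovascular simulator with
    time-varying ventricular elastance, ideal unidirectional valves and stiff implicit
    Radau integration; eigenvalue-based stiffness analysis of the linearized system;
    and an inVAErt network framework (neural emulator, Real-NVP normalizing-flow
    density estimator, variational encoder and decoder, all implemented in base R)
    for amortized inverse problems, structural and practical identifiability
    analysis of the non-identifiable parameter manifold, and density-ranked
    multiple imputation of missing clinical measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
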