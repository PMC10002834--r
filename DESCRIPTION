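Package: fontanflow
Title: Passive Hemodynamic Evaluation of Cavopulmonary Assist Devices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale computational pipeline for evaluating the passive
    (non-rotating, "failed pump") hemodynamic performance of a cavopulmonary
    assist device seated in an idealized total cavopulmonary connection.
    Generates labeled simplicial meshes for a four-port cross junction with an
    optional static biconical pump insert, solves steady and transient
    incompressible Newtonian flow with an equal-order stabilized finite-element
    method (SUPG/PSPG, resistance outflow, backflow stabilization,
    generalized-alpha time stepping), transports virtual dye by a stabilized
    advection-diffusion solver to map washout times, and extracts the standard
    shear-based thrombosis surrogates (TAWSS, OSI, low-WSS area fraction),
    pressure losses, flow splits and power loss.  Includes synthetic
    mock-circulatory-loop data generation and Bland-Altman agreement
    statistics for validating simulated pressure losses against bench
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    withr,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
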