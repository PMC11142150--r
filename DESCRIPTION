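Package: cortexflow
Title: Active-Fluid Modelling of Cytoskeletal Bulk Flow in Cell Motility
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state active-fluid model of one-dimensional cytoskeletal
    bulk flow driven by a Gaussian band of motor activity at a convergence
    zone, balanced by internal viscous stress and velocity-proportional
    adhesion traction. Provides closed-form stress and flow-speed estimates,
    a finite-difference boundary-value solver with no-gradient edge
    conditions, a staged procedure for fitting subcellular velocity profiles
    to recover adhesion, motor-strength and viscosity ratios, presets for
    five motility modes (cytokinesis, amoeboid, mesenchymal and neuronal
    migration, axon outgrowth), and generators for synthetic velocity
    profiles and kymograph-like tracer matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    signal,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
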