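Package: condcal
Type: Package
Title: Trust-Region Response-Surface Calibration of Cardiac Ionic Conductances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calibrates ionic current conductances of cardiac action-potential
    models by constrained optimization over second-order polynomial response
    surfaces with trust-region management. Surrogates of the objective (the
    squared one-cycle integral of the total potassium current) and of
    electrophysiological marker constraints (APD90, triangulation, calcium
    transient levels, APD rate-adaptation time constant) are fitted on full
    factorial databases and minimized inside an adaptively managed trust
    region. Includes a fully specified toy ventricular cell model with
    intracellular potassium dynamics, stiff-ODE pacing protocols, biomarker
    extraction, one-at-a-time conductance sensitivity analysis, synthetic
    fixtures with brute-force oracles, a CellML-subset model importer, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    parallel,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
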