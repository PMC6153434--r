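Package: hapabm
Title: Agent-Based PKPD Simulation of Hypoxia-Activated Prodrug Bystander
    Effects in 3D Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice agent-based pharmacokinetic/pharmacodynamic (PKPD)
    simulator for hypoxia-activated prodrugs (HAPs) such as SN30000 and
    PR104A in multicellular spheroid, monolayer and multicellular-layer
    (MCL) co-cultures of prodrug-activating and reductase-null target
    cells. Couples oxygen and drug/metabolite reaction-diffusion
    (Method-of-Lines on a cubic lattice with an unstirred medium column)
    to oxygen-dependent metabolism chains and per-cell clonogenic kill
    probabilities, supporting quantification of bystander effects,
    calibration of metabolism and potency constants from monolayer
    survival data, and generation of synthetic dose-response and
    diffusion-assay datasets for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
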