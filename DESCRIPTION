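Package: egfrpath
Title: Kinetic Modelling of EGFR-ERK Signalling and Gefitinib Response in
    H1299 Lung Cancer Cell Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation model of the
    EGFR-ERK signal transduction pathway (27 reaction steps, mass-action and
    Michaelis-Menten kinetics) in four H1299 non-small-cell lung cancer cell
    configurations: wild type, EGFR-overexpressing, and two L858R-mutant
    models distinguished by Mig6 or Cbl overexpression.  Provides stiff ODE
    simulation of EGF-stimulated phospho-protein time courses, western-blot
    style panel normalisation, a two-stage genetic-algorithm parameter
    estimation scheme with diversity control, gefitinib dose scans modelled
    as multiplicative inhibition of receptor autophosphorylation,
    upstream/downstream sensitivity-ratio indices, additive/antagonistic/
    synergistic classification of combined Mig6 and gefitinib perturbation,
    a synthetic pseudo-western-blot data generator with known ground truth,
    and SBML and declarative-YAML model exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
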