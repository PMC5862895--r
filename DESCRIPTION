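Package: pendelluft
Title: Cardiogenic Airflow, Pendelluft and Gas Mixing in Branching Airway Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cardiogenic oscillations and mechanical
    ventilation in the lung from dynamic (4D) image data, and for simulating
    their effect on gas mixing. The package generates synthetic double-gated
    lung imaging inputs with known ground truth (bifurcating airway trees,
    regional expansion fields, speckle image volumes, acquisition logs),
    performs retrospective cardiorespiratory double gating, measures regional
    tissue displacement and volumetric expansion by 3D cross-correlation
    velocimetry, propagates regional expansion into signed airflow through
    the airway tree by continuity, decomposes every bifurcation's flow into
    bulk and pendelluft components, and runs a Lagrangian gas-tracer
    transport model (Poiseuille advection with Runge-Kutta integration,
    random-walk molecular diffusion, trumpet-model peripheral airways with
    acinar compartments) to compute multi-breath washout curves and mixing
    enhancement ratios under diffusion-only, cardiac-only, ventilation-only
    and combined states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'pendelluft-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'tree.R'
    'expansion-field.R'
    'acquisition-log.R'
    'velocimetry.R'
    'airflow.R'
    'gating.R'
    'methods.R'
    'transport-geometry.R'
    'transport.R'
    'mixing.R'
    'speckle.R'
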