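Package: voxelmig
Title: Probabilistic Voxel Finite-Element Simulation of Single-Cell 3D Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lattice-based simulator of single-cell migration through a
    three-dimensional extracellular matrix. The cell is discretized as voxels
    embedded in a linear-elastic matrix and contracts through a two-spring
    acto-myosin mechanosensing law solved by trilinear hexahedral finite
    elements; voxels are stochastically gained and lost at the cell surface
    with probabilities driven by cell stress, the direction of maximum stress,
    chemical gradients and interstitial flow. Includes steady Darcy and
    advection-diffusion field solvers, ECM stiffness-gradient and degradation
    rules, a random porous-matrix generator, trajectory and shape metrics, and
    scenario orchestration with replicate management.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'voxelmig-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'domain.R'
    'mechanics.R'
    'dynamics.R'
    'io.R'
    'metrics.R'
    'remodeling.R'
    'transport.R'
    'scenarios.R'
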