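Package: memphase
Title: Phase Behavior of Two-Component Membranes Segmented by Adhesion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lattice-model thermodynamics of two-component lipid membranes
    whose adhesion to a surface splits them into two segments exposed to
    different environments. Provides exact square-lattice Ising results
    (critical temperature, spontaneous order parameter, binodals), a
    Bragg-Williams mean-field equation of state, solvers for the coupled
    partitioning and chemical-equilibrium relations between the segments,
    construction of phase diagrams in the composition-temperature plane,
    spherical-cap adhesion geometry for strongly adhering vesicles, and a
    seeded semi-grand-canonical Metropolis Monte Carlo simulator with an
    exact-enumeration oracle for small lattices.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
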