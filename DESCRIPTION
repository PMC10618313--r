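Package: dsbsim
Title: Coarse-Grained Dynamic Structure-Based Protein Simulation and
    Density Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implicit-solvent, one-bead-per-residue Langevin dynamics for
    dense multichain protein systems with dynamic structure-based (DSB)
    contacts: directional backbone/side-chain contact criteria, coordination
    limits, quasi-adiabatic contact switching, dynamic disulfides,
    Debye-Hueckel electrostatics and slab geometry with adhesive walls.
    Includes the full density-sweep protocol (self-avoiding-walk
    initialisation, quasi-static box squeezing, wall adhesion, oscillatory
    deformation) and the diagnostics used to choose an effective residue
    density for such systems: grid-of-balls cavity detection, pairwise
    entanglement counting by primitive-path shrinking, density profiles,
    radial distribution functions, chain shape metrics and a four-regime
    density classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    Biostrings,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
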