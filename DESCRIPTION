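Package: densref
Title: Density-Map Cross-Correlation Restraints for Simulated-Annealing
    Structure Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Flexible fitting of atomic models into low-resolution electron
    microscopy density maps. Implements a cross-correlation map potential
    (energy k_c(1 - C) between an observed map and a Gaussian-kernel map
    back-calculated from coordinates, with exact analytic gradients), CCP4/MRC
    and PDB input/output, flat-bottom distance restraints, a Cartesian
    simulated-annealing refinement engine with repeat-and-select ensemble
    generation, Kabsch superposition and ensemble precision/accuracy
    statistics, and synthetic helix fixtures with simulated maps for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
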