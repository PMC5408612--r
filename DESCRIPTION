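Package: nucbind
Title: Nucleosome-Ligand Binding Sites, Energetics, Hydration and Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for characterising small-molecule binding to the
    nucleosome core particle from ensemble-docking poses and molecular-dynamics
    output: average-linkage clustering of docked poses into candidate binding
    sites with contact-residue mapping, linear interaction energy (LIE) binding
    free-energy estimation with block-averaged errors and conversion between
    standard free energy and equilibrium constant, hydration-shell and
    site-occupancy water counting with apo/holo dewetting differences, and
    superposition-based RMSD/RMSF and C-alpha dynamic cross-correlation maps
    with classified apo-to-holo correlation changes. Includes synthetic-data
    generators (pseudo-nucleosome structures, autocorrelated energy series,
    planted pose clouds, water configurations, block-correlated trajectories)
    with known ground truth so every stage is testable without external data,
    plus fixed-column multi-model PDB input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
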