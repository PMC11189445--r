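Package: porekinetics
Title: Pore Geometry, Ion Permeation Kinetics and Gating Analysis for
    Channel Structures and Applied-Field Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of ion-channel structures and
    applied-field molecular-dynamics output: inscribed-sphere pore-radius
    profiling with per-residue constriction diameters, projection of cation
    trajectories into a pore-aligned frame with permeation-event counting
    and single-channel conductance estimation, axial free-energy profiles by
    Boltzmann inversion of ion densities, hydration, coordination-number and
    hydrogen-bond statistics along the pore, structural-comparison metrics
    (Kabsch superposition, RMSD/RMSF, helix bend angles, helix-coil
    detection), and single-Boltzmann fitting of activation curves. A
    synthetic-data module generates ring-built pores, kinked helices,
    solvation snapshots, Brownian-dynamics ion traces and activation-curve
    data with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
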