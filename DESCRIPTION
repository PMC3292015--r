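Package: mmgbsa
Title: Single-Trajectory MM-GBSA Binding Free Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of receptor-ligand binding by the
    molecular mechanics generalized Born surface area (MM-GBSA) method under
    the single-trajectory protocol: gas-phase molecular mechanics energies,
    Onufriev-Bashford-Case generalized Born polar solvation, Shrake-Rupley
    solvent-accessible surface area with a linear nonpolar term, normal-mode
    vibrational entropy, per-residue free-energy decomposition, computational
    alanine scanning by C-gamma truncation, hydrogen-bond occupancy analysis
    and backbone RMSD. Ships a synthetic-fixture generator (toy complexes,
    designed hydrogen-bond ensembles, Born-ion systems) so the whole pipeline
    is testable without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
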