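Package: foamygag
Title: Biophysical Analysis of Foamy Virus Gag N-Terminal Domain Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative solution biophysics and structural metrics for the
    obligate dimer formed by the N-terminal domain of the foamy (spuma)
    retrovirus Gag protein and its interaction with the envelope leader
    peptide. Provides closed-form hydrodynamic relations (Svedberg equation,
    anhydrous-sphere frictional ratios), a conservative finite-volume Lamm
    equation solver used both to simulate sedimentation velocity experiments
    and to invert them (discrete-species fits and Tikhonov-regularized
    sedimentation coefficient distributions), single-species sedimentation
    equilibrium simulation and global multi-speed fitting, quantitation of
    protein-peptide association constants from co-sedimenting absorbance,
    one-site isothermal titration calorimetry simulation and fitting,
    Shrake-Rupley solvent accessible surface area and buried interface area,
    Kabsch superposition RMSD, and the two-colour restriction-ratio statistic
    used in retroviral restriction assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
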