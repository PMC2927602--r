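Package: dimerdyn
Title: Elastic-Network Analysis of Protein-Protein Interface Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the fluctuation dynamics of residues at
    protein-protein interfaces with a beta-Gaussian elastic network model.
    Builds the two-centroid stiffness matrix for a dimeric complex, analytically
    integrates out the partner monomer (Schur complement) to obtain bound-form
    mobility in the subunit reference frame, rebuilds the quenched monomer
    network for the unbound form, classifies surface and interface residues
    from solvent-accessible surface areas, and computes the comparative
    statistics (RMSF distributions, bound-vs-unbound interpolating slopes,
    mobility scenarios) that discriminate interface types. Includes a seeded
    synthetic-dimer generator so the full pipeline runs offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
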