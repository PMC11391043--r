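Package: phbind
Title: pH-Dependent Ligand Binding and Conformational Dynamics of a Venom
    Carrier Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for pH-dependent ligand binding to small
    odorant-binding-like carrier proteins such as the fire-ant venom protein
    Sol g 2.1.  Fits fluorescence saturation and competitive-displacement
    titrations (one-site model, Scatchard diagnostics, Cheng-Prusoff Ki),
    computes trajectory descriptors (Kabsch-superposed RMSD, per-residue
    RMSF, radius of gyration, Shrake-Rupley SASA), aggregates MM-PBSA-style
    binding free-energy terms with an interaction-entropy estimate of -TdS
    and per-residue decomposition (the polar solvation term is a
    Generalized-Born surrogate), summarises per-residue pKa tables into
    Henderson-Hasselbalch protonation fractions and group averages, and
    performs two-component Cartesian principal component analysis of
    alpha-carbon coordinates.  A seeded synthetic-data generator produces
    toy receptor-ligand complexes, fluctuating trajectories, Gaussian
    interaction-energy series and noisy titration curves so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
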