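Package: pepscape
Title: Conformational Landscape Analysis of Helical Binding Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the conformational ensembles of short
    MDM2-binding peptides (p53 transactivation-domain variants and phage-derived
    12/1 variants) and of similar helix-forming peptides. Provides backbone
    construction from dihedral angles, Kabsch superposition RMSD, radius of
    gyration and helical-axis parameters; a Kabsch-Sander (DSSP-style)
    secondary-structure assignment; three ensemble helicity statistics;
    two-dimensional free-energy surfaces over Ramachandran or (RMSD, Rg)
    coordinates with watershed basin extraction; analysis of centre-of-mass
    pulling trajectories with jackknife errors and a helicity-retention
    classification; a desk-scale Hamiltonian replica-exchange (solute
    tempering) sampler on toy potentials; dissociation-constant to binding
    free-energy conversion; and a rule-based helix-propensity peptide
    redesign. A synthetic-ensemble generator with prescribed secondary
    structure populations makes every analysis stage testable without
    molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
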