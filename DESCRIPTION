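Package: gbsaHotspots
Title: MM/GBSA Binding Energetics, Per-Residue Decomposition and
    Hot-Spot Clustering for Protein-Ligand Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-stage analysis of protein-ligand snapshot ensembles in
    implicit solvent. Computes MM/GBSA interaction energies (pairwise
    Lennard-Jones and Coulomb terms, Generalized Born polar solvation with
    Hawkins-Cramer-Truhlar effective radii, and nonpolar solvation from
    solvent-accessible surface area by the LCPO analytic method or
    recursive icosahedral tessellation), decomposes binding energies per
    receptor residue, summarises snapshot ensembles with geometry monitors
    (superposition RMSD, distances, hydrogen-bond occupancy, pocket
    residues), clusters residue energy vectors across ligands with Ward
    linkage on Manhattan distances to identify shared hot-spot binding
    modes, and converts between inhibition constants, binding free
    energies, relative free energies and potency fold-changes. Ships
    seeded synthetic generators (toy pocket-ligand complexes, jittered
    ensembles, planted energy matrices) so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
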