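Package: CompDock
Title: Competitive Docking Model for Ensemble Receptor Virtual Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for competitive ensemble docking analysis of the human
    alpha7 nicotinic acetylcholine receptor ligand binding domain and related
    systems. Reads single- and multi-MODEL PDB structures, superposes and
    clusters binding-pocket conformations by pairwise RMSD with Ward linkage,
    fits a min-max normalized competitive docking model (CDM) on per-receptor
    docking score tables with a winning-score rule, classifies compounds as
    binders or non-binders, and detects geometric protein-ligand interactions
    (hydrophobic contacts, pi-pi stacking, pi-cation, hydrogen bonds) with
    per-residue interaction fractions, RMSD time series and RMSF profiles
    over trajectory-like frame ensembles. Includes deterministic synthetic
    fixture generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    igraph,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
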