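Package: lbvs
Title: Ligand-Based Virtual Screening and Target Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A ligand-based drug-repurposing pipeline. Curates
    database-style ligand corpora (DrugBank-, PDB- and ChEMBL-dialect
    tables), enumerates tautomer/stereoisomer states of a query scaffold,
    screens references by a five-fingerprint 2D Tanimoto consensus
    (MACCS, ECFP4, ECFP6, FCFP4, FCFP6) and by Gaussian-overlap 3D shape
    and pharmacophore-colour similarity (TanimotoCombo), joins hits
    across corpora by canonical isomeric SMILES keys, and ranks candidate
    protein targets by counts of similar active and inactive ligands.
    A synthetic-data module generates mock corpora with planted ground
    truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with RDKit, used for deterministic
    3D conformer embedding
Config/testthat/edition: 3
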