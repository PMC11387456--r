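Package: gpcrsift
Title: Structural Interaction Fingerprint Profiling of GPCR Ligand Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation and activity labeling of multi-source bioactivity
    collections (Ki/IC50/EC50), chemotype classification by substructure
    rules and fingerprint clustering, structural interaction fingerprint
    (SIFt) encoding of ligand-receptor complexes with GPCRdb generic
    residue numbering, contact-frequency and active/inactive differential
    statistics, rank correlation of contact frequency with activity,
    ligand RMSF analysis of trajectories, and confrontation with
    mutagenesis data. Includes seed-deterministic synthetic-data
    generators (activity tables, contact panels with planted signal, toy
    3D pockets, jittered trajectories) so every stage can be exercised
    and validated without external structure or database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    ggplot2,
    methods,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
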