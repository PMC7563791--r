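Package: trajmd
Title: Conformational Clustering and Interface Geometry for Protein Complex Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for molecular-dynamics trajectories of
    protein-protein complexes, centred on adenylyl-cyclase / G-protein
    systems but applicable to any two-chain complex. Implements GROMOS
    conformational clustering with dwell-time filtering, Kabsch
    superposition with RMSD/RMSF and displacement maps, Lee-Richards
    solvent-accessible surface area, interface area and Delta-ASA,
    SURFNET-style gap volume and gap index, helix-axis fitting with
    inter-helix angle and distance series, heavy-atom contact maps with
    conserved-contact and persistence statistics, named atom-pair distance
    monitors, and a config-driven pipeline. A synthetic-structure module
    generates trajectories with planted, recoverable properties for
    validation. Structures and trajectories are read and written as
    (multi-model) PDB.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
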