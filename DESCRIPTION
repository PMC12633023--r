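Package: iapScreen
Title: Interface-Adjacent Pocket Mining and Template-Based Molecular Glue Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines protein dimers for ligands bound in pockets adjacent to
    protein-protein interfaces, builds a template pocket/ligand library, and
    screens target dimers for candidate molecular glues by grid-based cavity
    detection, iterative pocket structural alignment with an empirical
    extreme-value p-value, template-based ligand pose transfer, and a
    calibration-table binding-precision estimate. Includes path-based
    fingerprint clustering of the mined ligand catalog and a deterministic
    synthetic-structure generator used for validation benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'structure-io.R'
    'interface.R'
    'pockets.R'
    'align.R'
    'sasa.R'
    'calibration.R'
    'screen.R'
    'fingerprint.R'
    'fixtures.R'
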