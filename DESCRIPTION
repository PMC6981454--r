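Package: comfa
Title: Comparative Molecular Field Analysis (CoMFA) 3D-QSAR for Purine Cytotoxicity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible CoMFA-style 3D-QSAR pipeline for small-molecule
    cytotoxicity data, built around a library of 2,6,9-trisubstituted purine
    derivatives screened against cancer cell lines. Provides compound and
    activity table readers with censoring-aware IC50 handling, deterministic
    3D conformer generation and Gasteiger charge assignment through Open
    Babel, rigid scaffold alignment, Lennard-Jones/Coulomb molecular
    interaction fields on a shared lattice, NIPALS partial least squares with
    leave-one-out cross-validation (q2) and external validation (r2pred),
    STDEV*COEFF contour extraction, Lipinski rule-of-five profiling,
    selectivity indices, exact-mass utilities, and a synthetic-data module
    with planted structure-activity relationships for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python with RDKit (python on the PATH) for seeded
    3D conformer embedding; Open Babel (obabel on the PATH) for partial
    charges, formulas and logP.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
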