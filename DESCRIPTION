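Package: contactpot
Title: Pairwise Residue Contact-Area Mean-Force Potentials for Protein
    Decoy Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes orientation-dependent pairwise residue contact areas
    in protein structures by probe-sphere point sampling over Van der Waals
    spheres, trains knowledge-based mean-force potentials from the observed
    contact areas (stratified by sequence separation and probe radius),
    scores structures with the trained potentials, and evaluates native-fold
    discrimination on decoy ensembles (native rank, Z-score, Pe, Kabsch
    RMSD).  Includes generators for idealized toy structures, planted-signal
    training corpora and perturbed decoy ensembles so the full pipeline runs
    without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
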