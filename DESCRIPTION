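Package: ssbridge
Title: Disulfide Bridge Engineering from Protein Backbone Geometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts residue pairs in a protein structure that could form a
    disulfide bond if mutated to cysteine. Side-chain sulfur positions are
    modeled from backbone and beta-carbon geometry alone by a chi1 x chi1'
    grid search with local refinement, candidate bridges are filtered on
    native disulfide geometry (S-S bond length, Cb-S-S angles, chi3 torsion
    windows), and each prediction is scored by a torsional energy function
    with chi3 minima at -87 and +97 degrees together with a summed B-factor
    mobility metric for ranking by expected stabilization. Includes PDB
    reading/writing with multi-model and SSBOND support, mutant structure
    export, a blind-validation survey harness, a deterministic generator of
    ideal-geometry test structures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
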