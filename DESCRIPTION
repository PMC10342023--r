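Package: strucleave
Title: Structural Susceptibility of Proteins to Proteolytic Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the susceptibility of each peptide bond of a folded
    protein to proteolytic cleavage from its 3D structure. Computes
    per-residue structural features (relative solvent accessibility,
    three-state secondary structure, normalized temperature factor,
    protruded-loop length, flexible N-/C-termini, and model confidence for
    predicted structures), maps experimentally observed proteolytic events
    onto structures, trains a linear discriminant scorer with balanced
    negative sampling and grouped cross-validation, builds protease
    primary-specificity position-specific scoring matrices, and fuses the
    structural and specificity scores with a Gaussian naive Bayes
    combiner. Includes a synthetic-structure generator with planted
    cleavage models for end-to-end benchmarking, readers and writers for
    fixed-column PDB and classic DSSP output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
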