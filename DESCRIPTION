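Package: harfia
Title: Hydrophilic Aromatic Residue Scoring and Feature-Incorporated
    Alignment for Carbohydrate-Binding Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based front end for homology modeling of
    carbohydrate-binding modules (CBMs). Scores aromatic residues by the
    weighted occurrence of their flanking residues to call hydrophilic
    aromatic residues (HARs, candidate ligand-binding residues), performs
    feature-incorporated global pairwise alignment (affine-gap
    Needleman-Wunsch/Gotoh over BLOSUM62 with bonuses at shared HAR and
    secondary-structure positions), filters templates by gap-penalized
    identity and similarity levels, enumerates single- and double-template
    model candidates scored through a pluggable structure-scorer contract,
    exports PIR alignments for external modeling engines, and evaluates
    HAR calls as a binding-residue predictor with ROC curves. Includes a
    seeded synthetic benchmark generator with planted binding motifs so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
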