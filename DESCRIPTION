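Package: lysace
Title: Position-Specific Prediction of Protein Lysine Acetylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for position-specific analysis and prediction of protein
    lysine acetylation sites from primary sequence. Extracts lysine-centered
    sequence windows from annotated proteins, encodes them with one-hot amino
    acid indicators, BLOSUM62-based k-nearest-neighbour similarity scores and
    an average accessible surface area index, ranks window offsets by
    information gain to build position-specific masks, and trains RBF-kernel
    support vector machines evaluated by balanced multi-negative-set 10-fold
    cross-validation with accuracy, sensitivity, specificity and the Matthews
    correlation coefficient. Includes a synthetic-data generator with planted
    positional motifs so the whole pipeline can be exercised and calibrated
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    withr
Config/testthat/edition: 3
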