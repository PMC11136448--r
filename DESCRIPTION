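Package: gatescribe
Title: Marker-Table Gating, Mining and Annotation for Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates flow and mass cytometry datasets from a marker table
    describing each cell type as a pseudo-gating strategy over protein
    markers (positive, medium, negative, or any level, with OR/XOR
    conditions). Expression levels are called per marker with univariate
    Gaussian mixture models, optionally preconditioned by ranked-set-sampling
    tail selection to counteract skewness; cells are matched against an
    ordered dictionary of concrete signatures, and unmatched or unsampled
    cells are refined with mutual-nearest-neighbour confident sets and k-NN
    classification, with an optional reject option that leaves genuinely
    novel populations labelled unknown. A training module mines a marker
    table from an annotated reference dataset using pairwise classification
    trees and greedy discriminant-marker selection, including three-level
    (medium) expression guided by suffixed labels. Includes readers and
    writers for CSV/FCS expression matrices and two marker-table dialects,
    evaluation metrics, a seeded synthetic-data generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
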