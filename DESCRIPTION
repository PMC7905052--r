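Package: ontofuse
Title: Automatic Alignment and Fusion of Cell Ontologies
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automatic fusion of two ontologies from the same knowledge
    domain, aimed at cell-type hierarchies that support single-cell atlas
    curation. Classes are aligned by scaled Levenshtein name matching
    (optionally maximised over synonym lists) combined with convolutional
    graph-structure matching over window-limited subgraphs, using one of five
    structure metrics (cosine, Euclidean and Pearson row convolution,
    constraint-based proximity weighting, or an iterative Blondel vertex
    similarity). Matched classes are unified and non-common classes and
    relations appended, with alignment evaluation (precision, recall, F-beta),
    a synthetic ontology-pair generator with known ground truth, an automatic
    ontology editor for scripted pre-processing, OWL (RDF/XML subset),
    spreadsheet and edge-list input, and an HTML/SVG merge report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite,
    optparse,
    parallel,
    withr,
    stringi,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
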