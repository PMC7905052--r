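#' @rdname OntologyGraph-accessors
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("classIds", function(x) standardGeneric("classIds"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("classSynonyms", function(x, id) standardGeneric("classSynonyms"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("ontologyName", function(x) standardGeneric("ontologyName"))

#' @rdname Subgraph-accessors
#' @export
setGeneric("generatorId", function(x) standardGeneric("generatorId"))

#' @rdname Subgraph-accessors
#' @export
setGeneric("nodeOrder", function(x) standardGeneric("nodeOrder"))

#' @rdname Subgraph-accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname Alignment-accessors
#' @export
setGeneric("alignmentRecords", function(x) standardGeneric("alignmentRecords"))

#' @rdname Alignment-accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @rdname MergeResult-accessors
#' @export
setGeneric("mergedOntology", function(x) standardGeneric("mergedOntology"))

#' @rdname MergeResult-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname SyntheticPair-accessors
#' @export
setGeneric("ontologyA", function(x) standardGeneric("ontologyA"))

#' @rdname SyntheticPair-accessors
#' @export
setGeneric("ontologyB", function(x) standardGeneric("ontologyB"))

#' @rdname SyntheticPair-accessors
#' @export
setGeneric("truthPairs", function(x) standardGeneric("truthPairs"))
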