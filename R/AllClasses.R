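#' @useDynLib ontofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' OntologyGraph: a labelled directed graph of classes
#'
#' The central container of the package. An ontology is stored as a set of
#' classes (each with an opaque unique id, a display label and an optional
#' list of synonyms) plus a set of directed parent-to-child edges. Well-formed
#' ontologies are DAGs, but ill-formed inputs (cycles, disconnected branches)
#' are tolerated: all graph operations terminate on arbitrary directed graphs.
#'
#' @slot classes data.frame with character columns \code{id} and \code{label},
#'   one row per class; ids are unique and non-empty.
#' @slot synonyms named list, one character vector per class (named by id);
#'   a synonym list never duplicates entries nor contains the class label.
#' @slot edges two-column character matrix (\code{parent}, \code{child});
#'   no self-loops, no duplicated rows, endpoints refer to existing classes.
#' @slot name free-text identifier of the ontology.
#'
#' @seealso [ontologyGraph()] for the user-facing constructor,
#'   [readOWL()], [readTwoColumn()] for file input.
#' @export
setClass("OntologyGraph",
  representation(
    classes  = "data.frame",
    synonyms = "list",
    edges    = "matrix",
    name     = "character"
  ),
  prototype(
    classes  = data.frame(id = character(), label = character(),
                          stringsAsFactors = FALSE),
    synonyms = list(),
    edges    = matrix(character(), ncol = 2,
                      dimnames = list(NULL, c("parent", "child"))),
    name     = "ontology"
  )
)

setValidity("OntologyGraph", function(object) {
  msg <- character()
  cl <- object@classes
  if (!all(c("id", "label") %in% names(cl)))
    return("classes must have 'id' and 'label' columns")
  ids <- cl$id
  if (anyDuplicated(ids)) msg <- c(msg, "class ids must be unique")
  if (any(!nzchar(ids))) msg <- c(msg, "class ids must be non-empty")
  if (!identical(sort(names(object@synonyms)), sort(ids)))
    msg <- c(msg, "synonyms must be a list named by the class ids")
  e <- object@edges
  if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0) {
    if (!all(e %in% ids))
      msg <- c(msg, "every edge endpoint must refer to an existing class")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loop edges are not allowed")
    if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  for (i in seq_along(ids)) {
    syn <- object@synonyms[[ids[i]]]
    if (anyDuplicated(syn) || cl$label[i] %in% syn) {
      msg <- c(msg, "synonym lists must not repeat entries or the class label")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Subgraph: a window-limited neighbourhood around a generator class
#'
#' Produced by [extractSubgraph()]. Holds the classes reachable from the
#' generator within W steps going only upstream (towards ancestors) or only
#' downstream (towards descendants), the induced edges, and the deterministic
#' node order used to build adjacency matrices: generator first, then
#' ascending breadth-first distance, ties broken by id.
#'
#' @slot generator id of the central class.
#' @slot nodeOrder ordered character vector of member ids, generator first.
#' @slot edges induced two-column character edge matrix.
#' @slot dist named integer vector: directed-sweep distance of each member to
#'   the generator (0 for the generator itself), aligned with \code{nodeOrder}.
#' @export
setClass("Subgraph",
  representation(
    generator = "character",
    nodeOrder = "character",
    edges     = "matrix",
    dist      = "integer"
  )
)

setValidity("Subgraph", function(object) {
  msg <- character()
  if (length(object@generator) != 1L || !nzchar(object@generator))
    msg <- c(msg, "generator must be a single non-empty id")
  no <- object@nodeOrder
  if (length(no) == 0L || no[1L] != object@generator)
    msg <- c(msg, "nodeOrder must start with the generator")
  if (anyDuplicated(no)) msg <- c(msg, "nodeOrder must not repeat members")
  if (length(object@dist) != length(no) ||
      !identical(names(object@dist), no))
    msg <- c(msg, "dist must be named by nodeOrder")
  if (nrow(object@edges) > 0 && !all(object@edges %in% no))
    msg <- c(msg, "edges must connect members only")
  if (length(msg)) msg else TRUE
})

#' FusionConfig: parameters of the alignment/merging run
#'
#' @slot W positive integer window length (default 4): the number of upstream
#'   or downstream edges from a generator node included in its subgraph.
#' @slot thetaN name-score threshold in \[0,1\] (default 0.85): a pair is a
#'   name match when its scaled Levenshtein similarity strictly exceeds it.
#' @slot thetaT structure-score threshold in \[0,1\] (default 0.7).
#' @slot thetaLN local-name threshold in \[0,1\] (default 0.7) used to confirm
#'   structure matches by the mean of best label similarities between the two
#'   subgraphs.
#' @slot metric one of \code{"cosine"}, \code{"euclidean"}, \code{"pearson"},
#'   \code{"constraint"}, \code{"blondel"}.
#' @slot useSynonyms take the max similarity over synonym lists.
#' @slot stopWords words removed whole-token by label normalisation.
#' @slot stripChars characters replaced by a space by label normalisation.
#' @slot synonymSep separator for inline synonym lists in tabular input.
#' @slot threads worker count for the structure-matrix loop (default 1).
#' @seealso [fusionConfig()], [readFusionConfig()]
#' @export
setClass("FusionConfig",
  representation(
    W           = "integer",
    thetaN      = "numeric",
    thetaT      = "numeric",
    thetaLN     = "numeric",
    metric      = "character",
    useSynonyms = "logical",
    stopWords   = "character",
    stripChars  = "character",
    synonymSep  = "character",
    threads     = "integer"
  )
)

.validMetrics <- c("cosine", "euclidean", "pearson", "constraint", "blondel")

setValidity("FusionConfig", function(object) {
  msg <- character()
  if (length(object@W) != 1L || is.na(object@W) || object@W < 1L)
    msg <- c(msg, "W must be a single integer >= 1")
  for (th in c("thetaN", "thetaT", "thetaLN")) {
    v <- slot(object, th)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", th))
  }
  if (length(object@metric) != 1L || !object@metric %in% .validMetrics)
    msg <- c(msg, sprintf("metric must be one of: %s",
                          paste(.validMetrics, collapse = ", ")))
  if (length(object@threads) != 1L || is.na(object@threads) ||
      object@threads < 1L)
    msg <- c(msg, "threads must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Alignment: per-class match decisions between two ontologies
#'
#' One record per class of ontology A with its best counterpart in B (if any),
#' the name and structure scores, and the match type (\code{"Name"},
#' \code{"Structure"} or \code{"Non-matched"}). A class of B may be the
#' partner of several classes of A; each class of A appears exactly once.
#'
#' @slot records data.frame with columns \code{nativeId}, \code{nativeLabel},
#'   \code{translatedId}, \code{translatedLabel}, \code{nameScore},
#'   \code{structureScore}, \code{matchType}.
#' @slot matchedPairs data.frame with columns \code{aId}, \code{bId},
#'   \code{matchType}, \code{score}: the matched (A, B) id pairs.
#' @export
setClass("Alignment",
  representation(records = "data.frame", matchedPairs = "data.frame")
)

setValidity("Alignment", function(object) {
  msg <- character()
  need <- c("nativeId", "nativeLabel", "translatedId", "translatedLabel",
            "nameScore", "structureScore", "matchType")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  r <- object@records
  if (anyDuplicated(r$nativeId))
    msg <- c(msg, "each A class must appear exactly once")
  if (!all(r$matchType %in% c("Name", "Structure", "Non-matched")))
    msg <- c(msg, "matchType must be Name, Structure or Non-matched")
  if (any(r$matchType == "Non-matched" & nzchar(r$translatedLabel)))
    msg <- c(msg, "Non-matched records must have an empty translated label")
  if (!all(c("aId", "bId") %in% names(object@matchedPairs)))
    msg <- c(msg, "matchedPairs must have aId and bId columns")
  if (length(msg)) msg else TRUE
})

#' MergeResult: a fused ontology plus merge statistics
#'
#' @slot merged the fused [OntologyGraph-class].
#' @slot nNameMatches number of A classes matched by name.
#' @slot nStructureMatches number of A classes matched by structure.
#' @slot nMatchedB number of distinct B classes matched to some A class.
#' @slot nSynonymPairs number of matched (A, B) pairs (>= nMatchedB when
#'   several A classes share one B partner).
#' @slot nAddedClasses B classes appended to A.
#' @slot nAddedRelations B relations added that were absent from A.
#' @slot provenance named character vector over merged class ids with values
#'   \code{"A"}, \code{"B"} or \code{"both"}.
#' @export
setClass("MergeResult",
  representation(
    merged            = "OntologyGraph",
    nNameMatches      = "integer",
    nStructureMatches = "integer",
    nMatchedB         = "integer",
    nSynonymPairs     = "integer",
    nAddedClasses     = "integer",
    nAddedRelations   = "integer",
    provenance        = "character"
  )
)

setValidity("MergeResult", function(object) {
  msg <- character()
  ids <- object@merged@classes$id
  if (!identical(sort(names(object@provenance)), sort(ids)))
    msg <- c(msg, "provenance must be named by the merged class ids")
  if (!all(object@provenance %in% c("A", "B", "both")))
    msg <- c(msg, "provenance values must be A, B or both")
  if (object@nAddedClasses != sum(object@provenance == "B"))
    msg <- c(msg, "nAddedClasses must equal the number of B-only classes")
  if (length(msg)) msg else TRUE
})

#' SyntheticPair: a generated ontology pair with known correspondences
#'
#' @slot ontoA,ontoB the two generated ontologies.
#' @slot truth data.frame (\code{aId}, \code{bId}) of true correspondences.
#' @slot params list of generation parameters, including the seed; the seed
#'   fully determines the pair.
#' @export
setClass("SyntheticPair",
  representation(
    ontoA  = "OntologyGraph",
    ontoB  = "OntologyGraph",
    truth  = "data.frame",
    params = "list"
  )
)

setValidity("SyntheticPair", function(object) {
  msg <- character()
  tr <- object@truth
  if (!all(c("aId", "bId") %in% names(tr)))
    return("truth must have aId and bId columns")
  if (nrow(tr) > 0) {
    if (!all(tr$aId %in% object@ontoA@classes$id))
      msg <- c(msg, "truth aId values must exist in ontoA")
    if (!all(tr$bId %in% object@ontoB@classes$id))
      msg <- c(msg, "truth bId values must exist in ontoB")
  }
  if (length(msg)) msg else TRUE
})
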