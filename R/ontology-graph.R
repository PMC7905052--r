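#' Construct an OntologyGraph
#'
#' User-facing constructor. Input irregularities that readers must tolerate
#' (duplicate edges, self-loops, synonym lists repeating the label) are
#' cleaned here with a message rather than rejected, so that ill-formed
#' ontologies can still be ingested and repaired by the automatic ontology
#' editor ([applyEditScript()]).
#'
#' @param ids character vector of unique class ids.
#' @param labels character vector of display labels (same length as `ids`).
#' @param edges two-column character matrix or data.frame of parent-to-child
#'   relations, or `NULL` for an edgeless ontology.
#' @param synonyms named list of character vectors (by id); classes absent
#'   from the list get an empty synonym list.
#' @param name free-text ontology identifier.
#' @return An [OntologyGraph-class] object.
#' @examples
#' g <- ontologyGraph(c("a", "b"), c("stem cell", "neuron"),
#'                    edges = cbind("a", "b"))
#' nClasses(g)
#' @export
ontologyGraph <- function(ids, labels = ids, edges = NULL,
                          synonyms = list(), name = "ontology") {
  ids <- as.character(ids)
  labels <- as.character(labels)
  stopifnot(length(ids) == length(labels))
  if (anyDuplicated(ids))
    stop("class ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  syn <- rep(list(character()), length(ids))
  names(syn) <- ids
  for (id in intersect(names(synonyms), ids)) {
    s <- unique(as.character(synonyms[[id]]))
    s <- s[nzchar(s) & s != labels[match(id, ids)]]
    syn[[id]] <- s
  }
  e <- .cleanEdges(edges, ids)
  new("OntologyGraph",
      classes = data.frame(id = ids, label = labels, stringsAsFactors = FALSE),
      synonyms = syn, edges = e, name = as.character(name)[1L])
}

# normalise an edge input to a deduplicated 2-column character matrix;
# self-loops and rows naming unknown classes are dropped with a message
.cleanEdges <- function(edges, ids) {
  empty <- matrix(character(), ncol = 2,
                  dimnames = list(NULL, c("parent", "child")))
  if (is.null(edges) || NROW(edges) == 0) return(empty)
  e <- as.matrix(edges)
  if (ncol(e) != 2) stop("edges must have exactly two columns")
  mode(e) <- "character"
  colnames(e) <- c("parent", "child")
  rownames(e) <- NULL
  bad <- !(e[, 1] %in% ids) | !(e[, 2] %in% ids)
  if (any(bad)) {
    message(sum(bad), " edge(s) with unknown endpoints dropped")
    e <- e[!bad, , drop = FALSE]
  }
  loops <- e[, 1] == e[, 2]
  if (any(loops)) {
    message(sum(loops), " self-loop edge(s) dropped")
    e <- e[!loops, , drop = FALSE]
  }
  dup <- duplicated(paste(e[, 1], e[, 2], sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed")
    e <- e[!dup, , drop = FALSE]
  }
  e
}

#' Accessors for OntologyGraph objects
#'
#' @param x an [OntologyGraph-class].
#' @param id a class id (for `classSynonyms`).
#' @return `nClasses`/`nEdges` return integers; `classIds` and `classLabels`
#'   character vectors (labels named by id); `classSynonyms` the synonym list
#'   of one class (or the full named list when `id` is missing); `edgeTable`
#'   the two-column character edge matrix; `ontologyName` the identifier.
#' @name OntologyGraph-accessors
NULL

#' @rdname OntologyGraph-accessors
#' @export
setMethod("nClasses", "OntologyGraph", function(x) nrow(x@classes))

#' @rdname OntologyGraph-accessors
#' @export
setMethod("nEdges", "OntologyGraph", function(x) nrow(x@edges))

#' @rdname OntologyGraph-accessors
#' @export
setMethod("classIds", "OntologyGraph", function(x) x@classes$id)

#' @rdname OntologyGraph-accessors
#' @export
setMethod("classLabels", "OntologyGraph", function(x) {
  structure(x@classes$label, names = x@classes$id)
})

#' @rdname OntologyGraph-accessors
#' @export
setMethod("classSynonyms", "OntologyGraph", function(x, id) {
  if (missing(id)) return(x@synonyms)
  if (!id %in% x@classes$id) stop("class not found: ", id)
  x@synonyms[[id]]
})

#' @rdname OntologyGraph-accessors
#' @export
setMethod("edgeTable", "OntologyGraph", function(x) x@edges)

#' @rdname OntologyGraph-accessors
#' @export
setMethod("ontologyName", "OntologyGraph", function(x) x@name)

setMethod("show", "OntologyGraph", function(object) {
  cat(sprintf("OntologyGraph '%s': %d classes, %d relations\n",
              object@name, nrow(object@classes), nrow(object@edges)))
  nsyn <- sum(lengths(object@synonyms) > 0)
  if (nsyn > 0) cat(sprintf("  %d classes carry synonyms\n", nsyn))
  if (nrow(object@classes) > 0) {
    k <- head(object@classes$label, 4L)
    cat("  labels: ", paste(k, collapse = "; "),
        if (nrow(object@classes) > 4L) "; ..." else "", "\n", sep = "")
  }
})

# internal: igraph view of an ontology (vertex name = class id)
.ontoIgraph <- function(onto) {
  igraph::graph_from_data_frame(
    d = as.data.frame(onto@edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = onto@classes$id, stringsAsFactors = FALSE)
  )
}
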