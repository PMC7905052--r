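#' Extract the window-W subgraph around a generator class
#'
#' Collects every class reachable from `node` by at most `W` edges traversed
#' either all-downstream (towards descendants) or all-upstream (towards
#' ancestors), together with the induced edges. Mixed-direction paths are
#' deliberately excluded: at W = 1 the window holds parents and children but
#' not siblings. The node order of the result is deterministic — generator
#' first, then ascending breadth-first distance, ties broken by id — so the
#' adjacency matrices derived from it are reproducible across runs.
#'
#' @param onto an [OntologyGraph-class].
#' @param node id of the generator class.
#' @param W non-negative integer window length.
#' @return A [Subgraph-class].
#' @examples
#' chain <- ontologyGraph(letters[1:5],
#'                        edges = cbind(letters[1:4], letters[2:5]))
#' nodeOrder(extractSubgraph(chain, "c", 1))  # "c" "b" "d"
#' @export
extractSubgraph <- function(onto, node, W) {
  stopifnot(is(onto, "OntologyGraph"))
  if (!node %in% onto@classes$id) stop("class not found: ", node)
  W <- as.integer(W)
  stopifnot(length(W) == 1L, !is.na(W), W >= 0L)
  g <- .ontoIgraph(onto)
  .extractSubgraphIg(g, onto@edges, node, W)
}

# workhorse on a prebuilt igraph; used by the batch paths to avoid
# rebuilding the graph for every generator
.extractSubgraphIg <- function(g, edges, node, W) {
  down <- igraph::ego(g, order = W, nodes = node, mode = "out")[[1]]$name
  up   <- igraph::ego(g, order = W, nodes = node, mode = "in")[[1]]$name
  members <- union(down, up)
  keep <- edges[, 1] %in% members & edges[, 2] %in% members
  subEdges <- edges[keep, , drop = FALSE]
  if (length(members) == 1L) {
    d <- 0L
    names(d) <- node
    return(new("Subgraph", generator = node, nodeOrder = node,
               edges = subEdges[0, , drop = FALSE], dist = d))
  }
  sg <- igraph::induced_subgraph(g, members)
  dOut <- igraph::distances(sg, v = node, to = members, mode = "out")[1, ]
  dIn  <- igraph::distances(sg, v = node, to = members, mode = "in")[1, ]
  d <- pmin(dOut, dIn)
  ord <- order(d, members)
  members <- members[ord]
  d <- as.integer(d[ord])
  names(d) <- members
  new("Subgraph", generator = node, nodeOrder = members,
      edges = subEdges, dist = d)
}

#' Accessors for Subgraph objects
#'
#' @param x a [Subgraph-class].
#' @name Subgraph-accessors
NULL

#' @rdname Subgraph-accessors
#' @export
setMethod("generatorId", "Subgraph", function(x) x@generator)

#' @rdname Subgraph-accessors
#' @export
setMethod("nodeOrder", "Subgraph", function(x) x@nodeOrder)

#' @describeIn Subgraph-accessors binary adjacency matrix in node order:
#'   entry (p, q) is 1 iff the induced edge order\[p\] -> order\[q\] exists.
#' @export
setMethod("adjacencyMatrix", "Subgraph", function(x) {
  n <- length(x@nodeOrder)
  m <- matrix(0, n, n, dimnames = list(x@nodeOrder, x@nodeOrder))
  if (nrow(x@edges) > 0) {
    p <- match(x@edges[, 1], x@nodeOrder)
    q <- match(x@edges[, 2], x@nodeOrder)
    m[cbind(p, q)] <- 1
  }
  m
})

setMethod("show", "Subgraph", function(object) {
  cat(sprintf("Subgraph around '%s': %d members, %d induced edges, max dist %d\n",
              object@generator, length(object@nodeOrder), nrow(object@edges),
              max(object@dist)))
})

#' Shortest path from a member to the generator
#'
#' Minimum edge count from `node` back to the generator within the extracted
#' subgraph, with edges traversed in the orientation used during extraction
#' (all-upstream or all-downstream). This is the proximity s used by the
#' constraint-based structure metric, where each match is weighted
#' c = W + 1 - s.
#'
#' @param sub a [Subgraph-class].
#' @param node a member id.
#' @return Non-negative integer; 0 iff `node` is the generator.
#' @export
shortestPathToGenerator <- function(sub, node) {
  stopifnot(is(sub, "Subgraph"))
  if (!node %in% sub@nodeOrder)
    stop("node not in subgraph: ", node)
  unname(sub@dist[[node]])
}
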