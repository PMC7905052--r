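.metricCode <- function(metric) {
  code <- match(metric, c("cosine", "euclidean", "pearson")) - 1L
  if (is.na(code))
    stop("metric must be cosine, euclidean or pearson; got: ", metric)
  code
}

#' Row convolution of two adjacency rows
#'
#' Slides the shorter binary row over the longer one at every offset and
#' scores each slide with the chosen vector metric against the aligned
#' window. The number of slides is `nc = |lenA - lenB| + 1` and the result
#' keeps every per-slide score together with their maximum. Scores lie in
#' \[0,1\]: cosine similarity (1 when both windows are all-zero, 0 when
#' exactly one is), Euclidean similarity `1 - d/sqrt(L)` with `L` the
#' compared length (the largest possible distance between binary vectors of
#' that length), and Pearson correlation clamped to \[0,1\] (zero-variance
#' windows score 1 iff identical).
#'
#' @param rowA,rowB non-empty binary numeric vectors.
#' @param metric one of "cosine", "euclidean", "pearson".
#' @return A list of class `"ConvolutionResult"` with fields `nc`,
#'   `scores` (length `nc`) and `best = max(scores)`.
#' @examples
#' rowConvolution(c(1, 0, 0, 1), 1)$nc  # 4
#' @export
rowConvolution <- function(rowA, rowB, metric = "cosine") {
  if (length(rowA) == 0 || length(rowB) == 0)
    stop("rows must be non-empty")
  out <- .rowConvolutionCpp(as.numeric(rowA), as.numeric(rowB),
                            .metricCode(metric))
  structure(out, class = "ConvolutionResult")
}

#' @export
print.ConvolutionResult <- function(x, ...) {
  cat(sprintf("ConvolutionResult: nc=%d, best=%.4f\n", x$nc, x$best))
  invisible(x)
}

#' Vectorial subgraph similarity based on graph convolution
#'
#' For every row of one subgraph's adjacency matrix, takes the best
#' [rowConvolution()] score against all rows of the other subgraph's matrix,
#' and averages those per-row maxima. The average is computed in both
#' directions and the two means averaged, which makes the score symmetric
#' and penalises size mismatch. Identical subgraphs (same node order) score
#' exactly 1.
#'
#' @param subA,subB [Subgraph-class] objects.
#' @param metric "cosine", "euclidean" or "pearson".
#' @return A similarity in \[0,1\].
#' @export
vectorialSimilarity <- function(subA, subB, metric = "cosine") {
  stopifnot(is(subA, "Subgraph"), is(subB, "Subgraph"))
  .vectorialSimAdj(adjacencyMatrix(subA), adjacencyMatrix(subB),
                   .metricCode(metric))
}

.vectorialSimAdj <- function(mA, mB, code) {
  (.vectorialDirectedCpp(mA, mB, code) +
   .vectorialDirectedCpp(mB, mA, code)) / 2
}

#' Constraint-based subgraph similarity
#'
#' Scores the structural correspondence of two generator nodes by the name
#' matches among their subgraph members, weighted by proximity to the
#' generator: a member k at shortest-path distance s contributes the
#' constraint `c = W + 1 - s`. The accumulated constraint is normalised by
#' the maximum attainable sum, `(min(|subA|, |subB|) - 1) * W` (every
#' non-generator node of the smaller subgraph matched at distance 1), and
#' clamped to \[0,1\]. Zero when no member pair exceeds the name threshold.
#'
#' @param subA,subB [Subgraph-class] objects.
#' @param S name matrix covering the member pairs (rows: A ids, cols: B ids).
#' @param thetaN name threshold; a member pair counts when `S > thetaN`.
#' @param W the window length used to extract the subgraphs.
#' @return A similarity in \[0,1\].
#' @export
constraintSimilarity <- function(subA, subB, S, thetaN, W) {
  stopifnot(is(subA, "Subgraph"), is(subB, "Subgraph"), W >= 1)
  ka <- subA@nodeOrder
  lb <- subB@nodeOrder
  if (!all(ka %in% rownames(S)) || !all(lb %in% colnames(S)))
    stop("S must cover all member pairs of the two subgraphs")
  sub <- S[ka, lb, drop = FALSE]
  matchedK <- ka[.rowMax(sub) > thetaN]
  if (length(matchedK) == 0) return(0)
  s <- subA@dist[matchedK]
  C <- sum(W + 1 - s)
  denom <- (min(length(ka), length(lb)) - 1) * W
  if (denom <= 0) return(0)
  min(1, C / denom)
}

#' Blondel subgraph similarity
#'
#' Iterative mutually-reinforcing vertex similarity between two subgraphs,
#' adapted to windowed subgraphs: starting from an all-ones matrix, iterate
#' \deqn{T_{k+1} = (B T_k A^t + B^t T_k A) / ||B T_k A^t + B^t T_k A||_F}
#' where A and B are the adjacency matrices of the two subgraphs, stopping at
#' the first even step k with `||T_k - T_{k-2}||_F < tol` (or at `maxIter`).
#' The returned score is the entry pairing the two generator nodes (first
#' position of each node order). When the iteration collapses to zero (an
#' edgeless subgraph), the score is 1 for two single-node subgraphs and 0
#' otherwise.
#'
#' @param subA,subB [Subgraph-class] objects.
#' @param tol convergence tolerance on the Frobenius norm (default 1e-6).
#' @param maxIter even iteration cap (default 100).
#' @return A similarity in \[0,1\].
#' @export
blondelSimilarity <- function(subA, subB, tol = 1e-6, maxIter = 100L) {
  stopifnot(is(subA, "Subgraph"), is(subB, "Subgraph"))
  .blondelAdj(adjacencyMatrix(subA), adjacencyMatrix(subB), tol, maxIter)
}

.blondelAdj <- function(mA, mB, tol = 1e-6, maxIter = 100L) {
  maxIter <- as.integer(maxIter)
  if (maxIter < 2L || maxIter %% 2L != 0L)
    stop("maxIter must be an even integer >= 2")
  na <- nrow(mA)
  nb <- nrow(mB)
  if (all(mA == 0) || all(mB == 0)) {
    if (na > 1 || nb > 1)
      message("edgeless subgraph in Blondel iteration: score 0")
    return(if (na == 1 && nb == 1) 1 else 0)
  }
  tA <- t(mA)
  tB <- t(mB)
  Tk <- matrix(1, nb, na)
  prevEven <- Tk
  for (k in seq_len(maxIter)) {
    num <- mB %*% Tk %*% tA + tB %*% Tk %*% mA
    nrm <- sqrt(sum(num * num))
    if (nrm == 0) return(0)
    Tk <- num / nrm
    if (k %% 2L == 0L) {
      if (sqrt(sum((Tk - prevEven)^2)) < tol) break
      prevEven <- Tk
    }
  }
  Tk[1L, 1L]
}

#' Build the structure mapping matrix
#'
#' Computes the matrix T of subgraph-structure similarities between the
#' name-unmatched (generator) classes of A and of B: around every generator a
#' window-W subgraph is extracted and each (i, j) entry scored with the
#' configured metric. Rows and columns are exactly the name-unmatched class
#' ids of A and B; an empty matrix results when one side has none (merging
#' then degenerates to name-only).
#'
#' Entries are independent, so with `cfg@threads > 1` columns are scored by a
#' forked worker pool; results are identical to serial execution.
#'
#' @param A,B [OntologyGraph-class] objects.
#' @param S name matrix from [buildNameMatrix()]; determines the generator
#'   sets through `cfg@thetaN` and supplies the name scores used by the
#'   constraint metric.
#' @param cfg a [FusionConfig-class].
#' @return Numeric matrix with rownames/colnames the generator ids, entries
#'   in \[0,1\].
#' @export
buildStructureMatrix <- function(A, B, S, cfg = fusionConfig()) {
  stopifnot(is(A, "OntologyGraph"), is(B, "OntologyGraph"))
  phase <- .namePhase(S, cfg@thetaN)
  gensA <- phase$unmatchedA
  gensB <- phase$unmatchedB
  if (length(gensA) == 0 || length(gensB) == 0) {
    message("no name-unmatched classes on one side: empty structure matrix")
    return(matrix(numeric(), length(gensA), length(gensB),
                  dimnames = list(gensA, gensB)))
  }
  subsA <- .extractAll(A, gensA, cfg@W)
  subsB <- .extractAll(B, gensB, cfg@W)
  metric <- cfg@metric
  if (metric %in% c("cosine", "euclidean", "pearson")) {
    code <- .metricCode(metric)
    adjA <- lapply(subsA, adjacencyMatrix)
    adjB <- lapply(subsB, adjacencyMatrix)
    colFun <- function(j) {
      vapply(adjA, .vectorialSimAdj, numeric(1), mB = adjB[[j]], code = code)
    }
  } else if (metric == "constraint") {
    colFun <- function(j) {
      vapply(subsA, constraintSimilarity, numeric(1), subB = subsB[[j]],
             S = S, thetaN = cfg@thetaN, W = cfg@W)
    }
  } else {  # blondel
    adjA <- lapply(subsA, adjacencyMatrix)
    adjB <- lapply(subsB, adjacencyMatrix)
    colFun <- function(j) {
      vapply(adjA, function(a) suppressMessages(.blondelAdj(a, adjB[[j]])),
             numeric(1))
    }
  }
  cols <- if (cfg@threads > 1L) {
    parallel::mclapply(seq_along(gensB), colFun, mc.cores = cfg@threads)
  } else {
    lapply(seq_along(gensB), colFun)
  }
  Tm <- do.call(cbind, cols)
  dimnames(Tm) <- list(gensA, gensB)
  Tm
}

# name-match phase shared by buildStructureMatrix and alignOntologies:
# best B partner per A row, strict > thetaN; ties at the row maximum break
# to the lexicographically smallest B id
.namePhase <- function(S, thetaN) {
  idsA <- rownames(S)
  idsB <- colnames(S)
  ordB <- order(idsB)
  best <- integer(nrow(S))
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    m <- max(row)
    best[i] <- ordB[which.max(row[ordB] == m)]
  }
  scores <- S[cbind(seq_len(nrow(S)), best)]
  matched <- scores > thetaN
  pairs <- data.frame(aId = idsA[matched], bId = idsB[best[matched]],
                      score = scores[matched], stringsAsFactors = FALSE)
  list(pairs = pairs, bestJ = idsB[best], bestScore = scores,
       unmatchedA = idsA[!matched],
       unmatchedB = setdiff(idsB, unique(pairs$bId)))
}

.extractAll <- function(onto, ids, W) {
  g <- .ontoIgraph(onto)
  out <- lapply(ids, function(id) .extractSubgraphIg(g, onto@edges, id, W))
  names(out) <- ids
  out
}
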