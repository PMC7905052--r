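# Independent oracles and small graph builders used across the suite.
# These deliberately avoid the code paths they check.

chainOntology <- function(n, ids = letters[seq_len(n)]) {
  ontologyGraph(ids, edges = if (n > 1) cbind(ids[-n], ids[-1]) else NULL)
}

# random DAG over n nodes: edges only from lower to higher index
randomDag <- function(n, pEdge = 0.15, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    e <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < pEdge) e <- rbind(e, c(ids[i], ids[j]))
      }
    }
    suppressMessages(ontologyGraph(ids, edges = e))
  })
}

# window membership by exhaustive enumeration of simple directed paths of
# length <= W, traversed all-downstream or all-upstream
oracleWindow <- function(onto, node, W) {
  e <- edgeTable(onto)
  walk <- function(cur, depth, down, visited) {
    if (depth == W) return(character(0))
    nxt <- if (down) e[e[, 1] == cur, 2] else e[e[, 2] == cur, 1]
    out <- character(0)
    for (v in nxt) {
      if (v %in% visited) next
      out <- c(out, v, walk(v, depth + 1L, down, c(visited, v)))
    }
    unique(out)
  }
  sort(unique(c(node, walk(node, 0L, TRUE, node),
                walk(node, 0L, FALSE, node))))
}

# textbook dynamic-programming edit distance, scalar
levOracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A)
  lb <- length(B)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la
  d[1L, ] <- 0:lb
  if (la > 0 && lb > 0) {
    for (i in seq_len(la)) {
      for (j in seq_len(lb)) {
        d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                                 d[i, j] + as.integer(A[i] != B[j]))
      }
    }
  }
  d[la + 1L, lb + 1L]
}

# all-pairs edit distance by a matrix-valued prefix DP: rows are strsA,
# columns strsB. Independent of utils::adist.
levOracleMatrix <- function(strsA, strsB) {
  maxLen <- max(nchar(c(strsA, strsB)))
  na <- length(strsA)
  nb <- length(strsB)
  chA <- matrix(NA_character_, na, maxLen)
  chB <- matrix(NA_character_, nb, maxLen)
  for (r in seq_len(na)) {
    s <- strsplit(strsA[r], "")[[1]]
    if (length(s)) chA[r, seq_along(s)] <- s
  }
  for (r in seq_len(nb)) {
    s <- strsplit(strsB[r], "")[[1]]
    if (length(s)) chB[r, seq_along(s)] <- s
  }
  lenA <- nchar(strsA)
  lenB <- nchar(strsB)
  D <- matrix(NA_integer_, na, nb)
  # prev[[j+1]] holds the DP matrix d[i-1, j]; cur[[j+1]] holds d[i, j]
  prev <- lapply(0:maxLen, function(j) matrix(j, na, nb))
  rowsDone <- lenA == 0L
  if (any(rowsDone)) D[rowsDone, ] <- rep(lenB, each = sum(rowsDone))
  for (i in seq_len(maxLen)) {
    cur <- vector("list", maxLen + 1L)
    cur[[1L]] <- matrix(i, na, nb)
    for (j in seq_len(maxLen)) {
      neq <- outer(chA[, i], chB[, j], "!=")
      cur[[j + 1L]] <- pmin(prev[[j + 1L]] + 1L, cur[[j]] + 1L,
                            prev[[j]] + neq)
    }
    hit <- which(lenA == i)
    if (length(hit)) {
      for (j in 0:maxLen) {
        cols <- which(lenB == j)
        if (length(cols)) D[hit, cols] <- cur[[j + 1L]][hit, cols]
      }
    }
    prev <- cur
  }
  D
}

# Blondel iteration through the Kronecker-product formulation:
# vec(B T A^t + B^t T A) = (K + K^t) vec(T) with K = A (x) B
blondelOracle <- function(mA, mB, tol = 1e-6, maxIter = 100L) {
  na <- nrow(mA)
  nb <- nrow(mB)
  if (all(mA == 0) || all(mB == 0))
    return(if (na == 1 && nb == 1) 1 else 0)
  K <- kronecker(mA, mB)
  M <- K + t(K)
  x <- rep(1, na * nb)
  prevEven <- x
  for (k in seq_len(maxIter)) {
    x <- as.vector(M %*% x)
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) return(0)
    x <- x / nrm
    if (k %% 2L == 0L) {
      if (sqrt(sum((x - prevEven)^2)) < tol) break
      prevEven <- x
    }
  }
  x[1L]  # column-major vec: entry (1, 1) of T
}

# a tiny raw RDF/XML document builder for reader tests
owlDoc <- function(body) {
  paste0('<?xml version="1.0"?>\n<rdf:RDF ',
         'xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
         'xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#" ',
         'xmlns:owl="http://www.w3.org/2002/07/owl#" ',
         'xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">\n',
         body, "\n</rdf:RDF>\n")
}

fixturePath <- function(f) system.file("extdata", f, package = "ontofuse")
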