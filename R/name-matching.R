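#' Levenshtein edit distance
#'
#' Classic edit distance: the minimum number of single-character insertions,
#' deletions and substitutions turning one string into the other. Symmetric
#' and satisfies the triangle inequality. Comparison is over Unicode code
#' points; inputs are NFC-normalised first so that composed and decomposed
#' accents compare equal. Vectorised over both arguments (recycled).
#'
#' @param a,b character vectors.
#' @return Integer vector of distances.
#' @examples
#' levenshteinDistance("kitten", "sitting")  # 3
#' @export
levenshteinDistance <- function(a, b) {
  a <- stringi::stri_trans_nfc(as.character(a))
  b <- stringi::stri_trans_nfc(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (n == 1L) return(as.integer(utils::adist(a, b)[1L]))
  vapply(seq_len(n), function(i) as.integer(utils::adist(a[i], b[i])[1L]),
         integer(1))
}

# full distance matrix between two string vectors (one C call)
.levMatrix <- function(a, b) {
  utils::adist(stringi::stri_trans_nfc(a), stringi::stri_trans_nfc(b))
}

#' Scaled name similarity
#'
#' The similarity between two labels is one minus the Levenshtein distance
#' scaled by the longer length:
#' \deqn{S(a, b) = 1 - lev(a, b) / \max(|a|, |b|)}
#' so identical strings score 1 and fully substituted strings of equal length
#' score 0. Two empty strings are defined as identical (similarity 1, with a
#' message).
#'
#' @param a,b character vectors (recycled).
#' @return Numeric vector of similarities in \[0,1\].
#' @examples
#' nameSimilarity("cells", "cell")  # 0.8
#' @export
nameSimilarity <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  mx <- pmax(nchar(a), nchar(b))
  bothEmpty <- mx == 0
  if (any(bothEmpty)) {
    message("both strings empty: similarity defined as 1")
    mx[bothEmpty] <- 1L
  }
  out <- 1 - levenshteinDistance(a, b) / mx
  out[bothEmpty] <- 1
  out
}

#' Best similarity over two synonym lists
#'
#' The similarity of two classes when synonyms are used: the maximum of
#' [nameSimilarity()] over all pairs from the two name lists. Each list must
#' include the principal label of its class (it always does when called
#' through [buildNameMatrix()]), so with empty synonym lists this reduces to
#' the similarity of the labels.
#'
#' @param listA,listB non-empty character vectors of names.
#' @return A single similarity in \[0,1\].
#' @export
synonymSimilarity <- function(listA, listB) {
  stopifnot(length(listA) > 0, length(listB) > 0)
  max(.simMatrix(listA, listB))
}

# similarity matrix (vectorised Eq. of nameSimilarity) between string vectors
.simMatrix <- function(a, b) {
  d <- .levMatrix(a, b)
  mx <- outer(nchar(a), nchar(b), pmax)
  bothEmpty <- mx == 0
  mx[bothEmpty] <- 1L
  s <- 1 - d / mx
  s[bothEmpty] <- 1
  s
}

#' Build the name mapping matrix between two ontologies
#'
#' Computes the a x b matrix of scaled Levenshtein similarities between every
#' class label of A and every class label of B. With `cfg@useSynonyms` the
#' entry is the maximum similarity over the two synonym lists (each including
#' the principal label), which can only increase entries. The full matrix is
#' materialised because local name matching later averages arbitrary entries.
#'
#' @param A,B non-empty [OntologyGraph-class] objects.
#' @param cfg a [FusionConfig-class].
#' @return Numeric matrix with rownames = class ids of A and colnames =
#'   class ids of B, entries in \[0,1\].
#' @export
buildNameMatrix <- function(A, B, cfg = fusionConfig()) {
  stopifnot(is(A, "OntologyGraph"), is(B, "OntologyGraph"))
  if (nClasses(A) == 0 || nClasses(B) == 0)
    stop("both ontologies must be non-empty")
  idsA <- A@classes$id
  idsB <- B@classes$id
  labA <- A@classes$label
  labB <- B@classes$label
  if (any(!nzchar(labA)) || any(!nzchar(labB)))
    warning("classes with empty labels present; their similarities use the ",
            "empty string")
  if (!cfg@useSynonyms) {
    S <- .simMatrix(labA, labB)
    dimnames(S) <- list(idsA, idsB)
    return(S)
  }
  namesA <- mapply(function(l, s) c(l, s), labA, A@synonyms[idsA],
                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  namesB <- mapply(function(l, s) c(l, s), labB, B@synonyms[idsB],
                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  grpA <- rep.int(seq_along(namesA), lengths(namesA))
  grpB <- rep.int(seq_along(namesB), lengths(namesB))
  full <- .simMatrix(unlist(namesA), unlist(namesB))
  # max-pool rows then columns down to one entry per class pair
  rowPooled <- matrix(NA_real_, length(namesA), ncol(full))
  for (g in seq_along(namesA)) {
    rows <- full[grpA == g, , drop = FALSE]
    rowPooled[g, ] <- .colMax(rows)
  }
  S <- matrix(NA_real_, length(namesA), length(namesB),
              dimnames = list(idsA, idsB))
  for (g in seq_along(namesB)) {
    cols <- rowPooled[, grpB == g, drop = FALSE]
    S[, g] <- .rowMax(cols)
  }
  S
}

.colMax <- function(m) apply(m, 2L, max)
.rowMax <- function(m) apply(m, 1L, max)
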