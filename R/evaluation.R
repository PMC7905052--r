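#' Confusion counts of a predicted alignment against a reference
#'
#' Pairs are compared as exact (A-id, B-id) tuples: TP are predicted pairs
#' present in the reference, FP predicted but absent, FN reference pairs
#' missed. Inputs may be data.frames/matrices with id columns `aId`, `bId`
#' (or the first two columns), or [Alignment-class] objects (their matched
#' pairs are used).
#'
#' @param predicted,reference pair sets.
#' @return A list of class `"ConfusionCounts"` with fields `TP`, `FP`, `FN`.
#' @export
confusionCounts <- function(predicted, reference) {
  p <- .pairKeys(predicted)
  r <- .pairKeys(reference)
  structure(list(TP = sum(p %in% r), FP = sum(!p %in% r),
                 FN = sum(!r %in% p)),
            class = "ConfusionCounts")
}

.pairKeys <- function(x) {
  if (is(x, "Alignment")) x <- x@matchedPairs
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (all(c("aId", "bId") %in% names(x))) {
    a <- x$aId; b <- x$bId
  } else {
    a <- x[[1]]; b <- x[[2]]
  }
  unique(paste(a, b, sep = "\r"))
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Precision, recall and the F-beta accuracy
#'
#' \deqn{Precision = TP/(TP+FP), \quad Recall = TP/(TP+FN)}
#' \deqn{F_\beta = (1+\beta^2) TP / ((1+\beta^2) TP + \beta^2 FN + FP)}
#' `fBeta` uses the count form, which equals the precision/recall form
#' wherever both are defined; beta > 1 emphasises recall, beta < 1
#' precision. Degenerate 0/0 cases are reported as 0 with a warning.
#'
#' @param counts a `"ConfusionCounts"` (or any list with TP, FP, FN).
#' @param beta positive weight of recall relative to precision.
#' @return A single value in \[0,1\].
#' @export
fBeta <- function(counts, beta = 1) {
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta <= 0)
    stop("beta must be a positive number")
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  denom <- (1 + beta^2) * tp + beta^2 * fn + fp
  if (denom == 0) {
    warning("no predicted and no reference pairs: F-beta defined as 0")
    return(0)
  }
  (1 + beta^2) * tp / denom
}

#' @rdname fBeta
#' @export
precisionScore <- function(counts) {
  d <- counts$TP + counts$FP
  if (d == 0) {
    warning("no predicted pairs: precision defined as 0")
    return(0)
  }
  counts$TP / d
}

#' @rdname fBeta
#' @export
recallScore <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) {
    warning("no reference pairs: recall defined as 0")
    return(0)
  }
  counts$TP / d
}

#' Score an alignment against a reference
#'
#' Convenience wrapper computing the confusion counts and the standard score
#' family: precision, recall, F1 (harmonic mean), F0.5 (precision-weighted)
#' and F2 (recall-weighted).
#'
#' @param predicted,reference pair sets (see [confusionCounts()]).
#' @return A named list: `counts`, `precision`, `recall`, `f1`, `f05`, `f2`.
#' @export
scoreAlignment <- function(predicted, reference) {
  cc <- confusionCounts(predicted, reference)
  list(counts = cc,
       precision = precisionScore(cc),
       recall = recallScore(cc),
       f1 = fBeta(cc, 1),
       f05 = fBeta(cc, 0.5),
       f2 = fBeta(cc, 2))
}
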