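#' Align two ontologies
#'
#' The decision cascade combining name and structure evidence. For every
#' class i of A the best name candidate j (largest entry of its row of S,
#' ties to the lexicographically smallest B id) is selected. If
#' `S[i, j] > thetaN` the pair is a name match. Otherwise the structure score
#' of that candidate is consulted: the pair is a structure match when both
#' classes are name-unmatched (generator nodes), `T[i, j] >= thetaT`, and the
#' local name comparison of their subgraphs confirms it
#' ([localNameConfirm()]). Anything else is non-matched. Matching is
#' one-directional (best per A class), so several A classes may share one B
#' partner.
#'
#' @param A,B [OntologyGraph-class] objects.
#' @param S name matrix from [buildNameMatrix()].
#' @param Tm structure matrix from [buildStructureMatrix()] (may be 0 x 0).
#' @param cfg a [FusionConfig-class].
#' @return An [Alignment-class] with one record per class of A.
#' @export
alignOntologies <- function(A, B, S, Tm, cfg = fusionConfig()) {
  stopifnot(is(A, "OntologyGraph"), is(B, "OntologyGraph"))
  phase <- .namePhase(S, cfg@thetaN)
  idsA <- rownames(S)
  labA <- classLabels(A)
  labB <- classLabels(B)
  gA <- .ontoIgraph(A)
  gB <- .ontoIgraph(B)
  subCacheB <- new.env(parent = emptyenv())
  n <- length(idsA)
  translatedId <- character(n)
  structureScore <- rep(NA_real_, n)
  matchType <- rep("Non-matched", n)
  nameMatched <- idsA %in% phase$pairs$aId
  for (i in seq_len(n)) {
    id <- idsA[i]
    j <- phase$bestJ[i]
    if (nameMatched[i]) {
      matchType[i] <- "Name"
      translatedId[i] <- j
      next
    }
    if (!(id %in% rownames(Tm)) || !(j %in% colnames(Tm))) next
    ts <- Tm[id, j]
    structureScore[i] <- ts
    if (ts < cfg@thetaT) next
    subA <- .extractSubgraphIg(gA, A@edges, id, cfg@W)
    subB <- .getSub(subCacheB, gB, B@edges, j, cfg@W)
    if (.localNameMean(subA, subB, S) > cfg@thetaLN) {
      matchType[i] <- "Structure"
      translatedId[i] <- j
    }
  }
  records <- data.frame(
    nativeId = idsA,
    nativeLabel = unname(labA[idsA]),
    translatedId = translatedId,
    translatedLabel = ifelse(nzchar(translatedId),
                             unname(labB[translatedId]), ""),
    nameScore = phase$bestScore,
    structureScore = structureScore,
    matchType = matchType,
    stringsAsFactors = FALSE
  )
  matched <- matchType != "Non-matched"
  pairs <- data.frame(
    aId = idsA[matched],
    bId = translatedId[matched],
    matchType = matchType[matched],
    score = ifelse(matchType[matched] == "Name",
                   phase$bestScore[matched], structureScore[matched]),
    stringsAsFactors = FALSE
  )
  new("Alignment", records = records, matchedPairs = pairs)
}

.getSub <- function(cache, g, edges, id, W) {
  if (is.null(cache[[id]]))
    cache[[id]] <- .extractSubgraphIg(g, edges, id, W)
  cache[[id]]
}

# mean over members k of A_W(i) of the best name score against B_W(j)
.localNameMean <- function(subA, subB, S) {
  ka <- intersect(subA@nodeOrder, rownames(S))
  lb <- intersect(subB@nodeOrder, colnames(S))
  if (length(ka) == 0 || length(lb) == 0) return(0)
  mean(.rowMax(S[ka, lb, drop = FALSE]))
}

#' Local name confirmation of a structure match
#'
#' Confirms a candidate structure pair (i, j) by label evidence in their
#' neighbourhoods: every member of the window-W subgraph around i takes its
#' best name score against the members of the subgraph around j, and the
#' pair is confirmed when the mean of those best scores strictly exceeds
#' `cfg@thetaLN`.
#'
#' @param A,B [OntologyGraph-class] objects.
#' @param i,j class ids in A and B.
#' @param S name matrix over all classes of A and B.
#' @param cfg a [FusionConfig-class] (uses `W` and `thetaLN`).
#' @return `TRUE` or `FALSE`.
#' @export
localNameConfirm <- function(A, B, i, j, S, cfg = fusionConfig()) {
  subA <- extractSubgraph(A, i, cfg@W)
  subB <- extractSubgraph(B, j, cfg@W)
  .localNameMean(subA, subB, S) > cfg@thetaLN
}

#' Accessors for Alignment objects
#'
#' @param x an [Alignment-class].
#' @name Alignment-accessors
NULL

#' @rdname Alignment-accessors
#' @export
setMethod("alignmentRecords", "Alignment", function(x) x@records)

#' @rdname Alignment-accessors
#' @export
setMethod("matchedPairs", "Alignment", function(x) x@matchedPairs)

setMethod("show", "Alignment", function(object) {
  tab <- table(factor(object@records$matchType,
                      levels = c("Name", "Structure", "Non-matched")))
  cat(sprintf("Alignment of %d classes: %d name, %d structure, %d non-matched\n",
              nrow(object@records), tab[["Name"]], tab[["Structure"]],
              tab[["Non-matched"]]))
})

#' Write the five-column alignment table
#'
#' Tab-separated with a header row and one row per class of A: native label,
#' translated label (empty when non-matched), name score, structure score
#' (both with 4 decimals, `NA` when never computed) and the assignment type
#' (`Name`, `Structure` or the literal `Non-matched`).
#'
#' @param al an [Alignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignmentTable <- function(al, path) {
  stopifnot(is(al, "Alignment"))
  r <- al@records
  out <- data.frame(
    native_label = r$nativeLabel,
    translated_label = r$translatedLabel,
    name_score = sprintf("%.4f", r$nameScore),
    structure_score = ifelse(is.na(r$structureScore), "NA",
                             sprintf("%.4f", r$structureScore)),
    match_type = r$matchType,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference alignment
#'
#' Two-column tab-separated file of matched (A-id, B-id) pairs; `#` starts a
#' comment. Duplicated pairs are collapsed with a warning.
#'
#' @param path path to the reference file.
#' @return data.frame with columns `aId`, `bId`.
#' @export
readReferenceAlignment <- function(path) {
  if (!file.exists(path)) stop("reference alignment not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  if (length(lines) == 0)
    return(data.frame(aId = character(), bId = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2))
    stop("reference alignment rows must have two tab-separated columns")
  df <- data.frame(aId = vapply(f, `[`, "", 1L),
                   bId = vapply(f, `[`, "", 2L), stringsAsFactors = FALSE)
  dup <- duplicated(paste(df$aId, df$bId, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicated reference pair(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  df
}
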