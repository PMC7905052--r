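#' Merge ontology B into ontology A using an alignment
#'
#' Matched B classes are unified with their A partners (the B label and
#' synonyms become synonyms of the A class, unless identical to its label);
#' unmatched B classes are appended under fresh deterministic ids (a prefix
#' plus a zero-padded counter, chosen to never collide with existing ids);
#' every B relation is re-expressed in merged ids and appended, dropping
#' duplicates (first-seen order preserved) and self-loops created by
#' unification. When several A classes match one B class, the B class is
#' unified with its best-scoring partner (ties to the lexicographically
#' smallest A id) rather than replicated.
#'
#' @param A,B [OntologyGraph-class] objects.
#' @param al an [Alignment-class] between A and B.
#' @return A [MergeResult-class]; the merged graph satisfies
#'   `|merged| = |A| + |B| - [distinct matched B classes]`.
#' @export
mergeOntologies <- function(A, B, al) {
  stopifnot(is(A, "OntologyGraph"), is(B, "OntologyGraph"),
            is(al, "Alignment"))
  pairs <- al@matchedPairs
  if (nrow(pairs) > 0 &&
      (!all(pairs$aId %in% A@classes$id) || !all(pairs$bId %in% B@classes$id)))
    stop("alignment references classes unknown to A or B")

  # one A partner per matched B class: best score, ties to smallest A id
  bMap <- character(0)
  if (nrow(pairs) > 0) {
    ord <- order(pairs$bId, -pairs$score, pairs$aId)
    first <- !duplicated(pairs$bId[ord])
    bMap <- structure(pairs$aId[ord][first], names = pairs$bId[ord][first])
  }
  matchedB <- names(bMap)
  unmatchedB <- setdiff(B@classes$id, matchedB)

  prefix <- "B:"
  while (any(startsWith(c(A@classes$id, B@classes$id), prefix)))
    prefix <- paste0("Z", prefix)
  freshIds <- sprintf("%s%04d", prefix, seq_along(unmatchedB))
  idMap <- c(bMap, structure(freshIds, names = unmatchedB))

  cl <- A@classes
  syn <- A@synonyms
  labB <- classLabels(B)
  for (b in matchedB) {
    a <- bMap[[b]]
    aLabel <- cl$label[cl$id == a]
    extra <- unique(c(labB[[b]], B@synonyms[[b]]))
    syn[[a]] <- setdiff(unique(c(syn[[a]], extra)), aLabel)
  }
  if (length(unmatchedB)) {
    cl <- rbind(cl, data.frame(id = freshIds,
                               label = unname(labB[unmatchedB]),
                               stringsAsFactors = FALSE))
    for (k in seq_along(unmatchedB))
      syn[[freshIds[k]]] <- B@synonyms[[unmatchedB[k]]]
  }

  e <- A@edges
  nEdgesA <- nrow(e)
  if (nrow(B@edges) > 0) {
    eb <- cbind(parent = unname(idMap[B@edges[, 1]]),
                child  = unname(idMap[B@edges[, 2]]))
    eb <- eb[eb[, 1] != eb[, 2], , drop = FALSE]
    e <- rbind(e, eb)
    e <- e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
  }

  merged <- new("OntologyGraph", classes = cl, synonyms = syn, edges = e,
                name = paste(A@name, B@name, sep = "+"))
  prov <- structure(rep("A", nrow(cl)), names = cl$id)
  prov[unname(bMap)] <- "both"
  prov[freshIds] <- "B"
  types <- al@records$matchType
  new("MergeResult",
      merged = merged,
      nNameMatches = sum(types == "Name"),
      nStructureMatches = sum(types == "Structure"),
      nMatchedB = length(matchedB),
      nSynonymPairs = nrow(pairs),
      nAddedClasses = length(unmatchedB),
      nAddedRelations = nrow(e) - nEdgesA,
      provenance = prov)
}

#' Accessors for MergeResult objects
#'
#' @param x a [MergeResult-class].
#' @name MergeResult-accessors
NULL

#' @rdname MergeResult-accessors
#' @export
setMethod("mergedOntology", "MergeResult", function(x) x@merged)

#' @rdname MergeResult-accessors
#' @export
setMethod("provenance", "MergeResult", function(x) x@provenance)

setMethod("show", "MergeResult", function(object) {
  cat(sprintf("MergeResult '%s': %d classes, %d relations\n",
              object@merged@name, nrow(object@merged@classes),
              nrow(object@merged@edges)))
  cat(sprintf("  matches: %d name + %d structure (%d distinct B classes)\n",
              object@nNameMatches, object@nStructureMatches,
              object@nMatchedB))
  cat(sprintf("  added: %d classes, %d relations\n",
              object@nAddedClasses, object@nAddedRelations))
})

#' Summary statistics of a merge
#'
#' Integer counts plus percentages (1 decimal) of the merge outcome: matches
#' by type relative to the size of A, matched/added B classes relative to
#' the size of B, and added relations relative to the relation count of A.
#' This list is the single source of truth for the JSON statistics file and
#' the HTML report.
#'
#' @param res a [MergeResult-class].
#' @param nA,nB class counts of the two inputs; taken from the provenance
#'   when omitted.
#' @param nRelA relation count of ontology A.
#' @return A named list of counts and percentages.
#' @export
mergeStats <- function(res, nA = NULL, nB = NULL, nRelA = NULL) {
  stopifnot(is(res, "MergeResult"))
  if (is.null(nA)) nA <- sum(res@provenance != "B")
  if (is.null(nB)) nB <- res@nMatchedB + res@nAddedClasses
  pct <- function(x, d) if (d > 0) round(100 * x / d, 1) else 0
  list(
    n_classes_A = as.integer(nA),
    n_classes_B = as.integer(nB),
    n_classes_merged = nrow(res@merged@classes),
    n_relations_merged = nrow(res@merged@edges),
    n_name_matches = res@nNameMatches,
    n_structure_matches = res@nStructureMatches,
    n_matched_B = res@nMatchedB,
    n_synonym_pairs = res@nSynonymPairs,
    n_added_classes = res@nAddedClasses,
    n_added_relations = res@nAddedRelations,
    pct_name_matches = pct(res@nNameMatches, nA),
    pct_structure_matches = pct(res@nStructureMatches, nA),
    pct_non_matched = pct(nA - res@nNameMatches - res@nStructureMatches, nA),
    pct_added_classes = pct(res@nAddedClasses, nB),
    pct_added_relations = if (!is.null(nRelA) && nRelA > 0)
      round(100 * res@nAddedRelations / nRelA, 1) else NA
  )
}
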