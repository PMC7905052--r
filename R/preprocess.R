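#' Normalise a class label
#'
#' Label preconditioning applied before name matching: lowercase, replace
#' each strip character by a space (so "yolk-sac" becomes "yolk sac" rather
#' than "yolksac"), drop stop words as whole tokens (case-insensitive, so
#' removing "cell" leaves "cellular" intact), collapse runs of whitespace and
#' trim. Idempotent. Typical stop words for cell ontologies are
#' "cell", "cells", "human"; typical strip characters "-", "/", ",".
#'
#' @param s character vector of labels.
#' @param stripChars character vector of single characters to replace by a
#'   space.
#' @param stopWords character vector of whole words to drop.
#' @return Character vector of normalised labels (possibly empty strings).
#' @examples
#' normalizeLabel("Hypoblast Cells", stopWords = c("cell", "cells"))
#' @export
normalizeLabel <- function(s, stripChars = character(),
                           stopWords = character()) {
  s <- tolower(as.character(s))
  for (ch in stripChars)
    s <- gsub(ch, " ", s, fixed = TRUE)
  if (length(stopWords)) {
    sw <- tolower(stopWords)
    s <- vapply(strsplit(s, "[[:space:]]+"), function(tok) {
      paste(tok[!(tok %in% sw)], collapse = " ")
    }, character(1))
  }
  trimws(gsub("[[:space:]]+", " ", s))
}

#' Read an ontology edit script
#'
#' One operation per line, fields separated by tabs:
#' \preformatted{
#' select<TAB>pattern
#' deselect<TAB>pattern
#' connect<TAB>parent name<TAB>child name
#' merge_classes<TAB>keep name<TAB>absorb name
#' normalize_labels<TAB>strip chars (comma-sep)<TAB>stop words (comma-sep)
#' }
#' `#` starts a comment. Patterns are case-insensitive substring matches
#' against labels and synonyms. Operations are applied strictly in order.
#'
#' @param path path to the edit-script text file.
#' @return A list of operations with class `"EditScript"`.
#' @export
readEditScript <- function(path) {
  if (!file.exists(path)) stop("edit script not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  ops <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    op <- f[1]
    switch(op,
      select   = list(op = "select", pattern = f[2]),
      deselect = list(op = "deselect", pattern = f[2]),
      connect  = list(op = "connect", parent = f[2], child = f[3]),
      merge_classes = list(op = "merge_classes", keep = f[2], absorb = f[3]),
      normalize_labels = list(op = "normalize_labels",
                              stripChars = .cfgList(.orEmpty(f[2])),
                              stopWords = .cfgList(.orEmpty(f[3]))),
      stop("unknown edit operation: ", op))
  })
  structure(ops, class = "EditScript")
}

.orEmpty <- function(x) if (length(x) == 0 || is.na(x)) "" else x

#' Edit script constructor
#'
#' Programmatic counterpart of [readEditScript()]: build an edit script from
#' operation lists, e.g. `editScript(list(op = "deselect", pattern = "immune"))`.
#'
#' @param ... operation lists, each with an `op` field.
#' @return An `"EditScript"` object.
#' @export
editScript <- function(...) {
  structure(list(...), class = "EditScript")
}

#' Apply an edit script to an ontology
#'
#' The "automatic ontology editor": scripted repair and label
#' preconditioning applied before alignment. Supported operations:
#' \describe{
#'   \item{select}{keep only classes whose label or a synonym contains the
#'     pattern (case-insensitive substring), with the induced edges.}
#'   \item{deselect}{remove matching classes and their incident edges.}
#'   \item{connect}{add one parent-to-child edge between two named classes.}
#'   \item{merge_classes}{absorb one class into another: the kept class
#'     inherits the union of edges and synonyms, the absorbed label becomes a
#'     synonym; self-loops created by the union are removed.}
#'   \item{normalize_labels}{apply [normalizeLabel()] to every label and
#'     synonym. A label that would normalise to the empty string is kept
#'     unchanged, with a warning.}
#' }
#' `connect` and `merge_classes` refer to classes by exact label (fallback:
#' id) and error when the class is absent.
#'
#' @param onto an [OntologyGraph-class].
#' @param script an `"EditScript"` from [readEditScript()] or [editScript()].
#' @return The edited [OntologyGraph-class].
#' @export
applyEditScript <- function(onto, script) {
  stopifnot(is(onto, "OntologyGraph"), inherits(script, "EditScript"))
  for (op in script) {
    onto <- switch(op$op,
      select   = .opSelect(onto, op$pattern, keep = TRUE),
      deselect = .opSelect(onto, op$pattern, keep = FALSE),
      connect  = .opConnect(onto, op$parent, op$child),
      merge_classes = .opMerge(onto, op$keep, op$absorb),
      normalize_labels = .opNormalize(onto, op$stripChars, op$stopWords),
      stop("unknown edit operation: ", op$op))
  }
  onto
}

# pattern matches label or any synonym, case-insensitive substring
.patternHits <- function(onto, pattern) {
  pat <- tolower(pattern)
  hitLab <- grepl(pat, tolower(onto@classes$label), fixed = TRUE)
  hitSyn <- vapply(onto@synonyms[onto@classes$id], function(s) {
    any(grepl(pat, tolower(s), fixed = TRUE))
  }, logical(1))
  hitLab | hitSyn
}

.opSelect <- function(onto, pattern, keep) {
  hits <- .patternHits(onto, pattern)
  take <- if (keep) hits else !hits
  if (keep && !any(hits))
    warning("select pattern matched no class: ", pattern)
  .subsetOntology(onto, onto@classes$id[take])
}

.subsetOntology <- function(onto, ids) {
  cl <- onto@classes[onto@classes$id %in% ids, , drop = FALSE]
  e <- onto@edges
  e <- e[e[, 1] %in% ids & e[, 2] %in% ids, , drop = FALSE]
  new("OntologyGraph", classes = cl, synonyms = onto@synonyms[cl$id],
      edges = e, name = onto@name)
}

.resolveClass <- function(onto, nm, what) {
  i <- which(onto@classes$label == nm)
  if (length(i) == 0) i <- which(onto@classes$id == nm)
  if (length(i) == 0)
    stop(what, " names a class absent from the ontology: ", nm)
  onto@classes$id[i[1L]]
}

.opConnect <- function(onto, parent, child) {
  p <- .resolveClass(onto, parent, "connect")
  c <- .resolveClass(onto, child, "connect")
  if (p == c) stop("connect would create a self-loop on: ", parent)
  e <- rbind(onto@edges, c(p, c))
  e <- e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
  colnames(e) <- c("parent", "child")
  initialize(onto, edges = e)
}

.opMerge <- function(onto, keepName, absorbName) {
  kid <- .resolveClass(onto, keepName, "merge_classes")
  aid <- .resolveClass(onto, absorbName, "merge_classes")
  if (kid == aid) return(onto)
  cl <- onto@classes
  keepLabel <- cl$label[cl$id == kid]
  absorbLabel <- cl$label[cl$id == aid]
  syn <- onto@synonyms
  merged <- unique(c(syn[[kid]], absorbLabel, syn[[aid]]))
  syn[[kid]] <- setdiff(merged, keepLabel)
  syn[[aid]] <- NULL
  e <- onto@edges
  e[e == aid] <- kid
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
  new("OntologyGraph", classes = cl[cl$id != aid, , drop = FALSE],
      synonyms = syn, edges = e, name = onto@name)
}

.opNormalize <- function(onto, stripChars, stopWords) {
  cl <- onto@classes
  norm <- normalizeLabel(cl$label, stripChars, stopWords)
  empty <- !nzchar(norm)
  if (any(empty)) {
    warning("normalisation would empty ", sum(empty),
            " label(s); kept unchanged: ",
            paste(head(cl$label[empty], 3), collapse = ", "))
    norm[empty] <- cl$label[empty]
  }
  cl$label <- norm
  syn <- onto@synonyms
  for (i in seq_len(nrow(cl))) {
    id <- cl$id[i]
    s <- normalizeLabel(syn[[id]], stripChars, stopWords)
    s <- unique(s[nzchar(s) & s != cl$label[i]])
    syn[[id]] <- s
  }
  new("OntologyGraph", classes = cl, synonyms = syn, edges = onto@edges,
      name = onto@name)
}
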