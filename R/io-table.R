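#' Read an ontology from a two-column parent/child table
#'
#' Each row holds the name of a class and the name of one of its children;
#' classes are the union of both columns, keyed by name (the name string is
#' the class id). Duplicate rows collapse to one edge; rows with an empty
#' cell are skipped with a warning; a single-column file is a format error.
#' A cell may carry an inline synonym list, `label|syn1|syn2`, split on
#' `synonymSep`; the first element names the class and the rest accumulate
#' as its synonyms.
#'
#' Supported dialects: `"tsv"` (tab-separated text, no header) and `"ods"`
#' (an OpenDocument spreadsheet, first sheet; both the zipped `.ods`
#' container and the flat-XML `.fods` form are accepted).
#'
#' @param path path to the table file.
#' @param dialect `"tsv"` or `"ods"`.
#' @param synonymSep separator of inline synonym lists (default `"|"`).
#' @param name ontology identifier; defaults to the file name.
#' @return An [OntologyGraph-class].
#' @export
readTwoColumn <- function(path, dialect = c("tsv", "ods"),
                          synonymSep = "|", name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("table file not found: ", path)
  rows <- switch(dialect,
                 tsv = .readTsvRows(path),
                 ods = .readOdsRows(path))
  if (length(rows) == 0) stop("table has no data rows: ", path)
  if (any(lengths(rows) == 1))
    stop("two columns required but a single-column row found in: ", path)
  parent <- vapply(rows, `[`, "", 1L)
  child <- vapply(rows, `[`, "", 2L)
  empty <- !nzchar(trimws(parent)) | !nzchar(trimws(child))
  if (any(empty)) {
    warning(sum(empty), " row(s) with an empty cell skipped")
    parent <- parent[!empty]
    child <- child[!empty]
  }
  if (length(parent) == 0) stop("no usable rows in: ", path)
  synonyms <- list()
  splitCell <- function(cell) {
    parts <- trimws(strsplit(cell, synonymSep, fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    nm <- parts[1L]
    if (length(parts) > 1)
      synonyms[[nm]] <<- unique(c(synonyms[[nm]], parts[-1L]))
    nm
  }
  parent <- vapply(parent, splitCell, "", USE.NAMES = FALSE)
  child <- vapply(child, splitCell, "", USE.NAMES = FALSE)
  ids <- unique(c(parent, child))
  ontologyGraph(ids, ids, edges = cbind(parent, child),
                synonyms = synonyms, name = name)
}

.readTsvRows <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad them back
    want <- lengths(regmatches(ln, gregexpr("\t", ln, fixed = TRUE))) + 1L
    c(parts, rep("", max(0L, want - length(parts))))
  })
}

# ODS: zipped container (content.xml member) or flat-XML .fods single file
.readOdsRows <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  doc <- if (identical(rawToChar(magic), "PK")) {
    con <- unz(path, "content.xml")
    on.exit(close(con), add = TRUE)
    xml2::read_xml(paste(readLines(con, warn = FALSE), collapse = "\n"))
  } else {
    xml2::read_xml(path)
  }
  ns <- c(
    table = "urn:oasis:names:tc:opendocument:xmlns:table:1.0",
    text = "urn:oasis:names:tc:opendocument:xmlns:text:1.0"
  )
  tbl <- xml2::xml_find_first(doc, ".//table:table", ns = ns)
  if (inherits(tbl, "xml_missing"))
    stop("no spreadsheet table found in: ", path)
  rowsXml <- xml2::xml_find_all(tbl, "./table:table-row", ns = ns)
  rows <- lapply(rowsXml, function(r) {
    cells <- xml2::xml_find_all(r, "./table:table-cell", ns = ns)
    vals <- character(0)
    for (cell in cells) {
      rep <- xml2::xml_attr(cell, "number-columns-repeated")
      n <- if (is.na(rep)) 1L else as.integer(rep)
      txt <- paste(xml2::xml_text(
        xml2::xml_find_all(cell, ".//text:p", ns = ns)), collapse = " ")
      vals <- c(vals, rep(txt, n))
      if (length(vals) >= 2L) break  # only the first two columns matter
    }
    vals[seq_len(min(2L, max(1L, length(vals))))]
  })
  rows <- rows[vapply(rows, function(v) any(nzchar(v)), logical(1))]
  rows
}
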