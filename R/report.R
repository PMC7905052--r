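#' Render the HTML merge report
#'
#' Writes a single self-contained HTML file with the merge statistics in a
#' table, a donut chart of the match breakdown (green: name matches, red:
#' structure matches, grey: non-matched), and a static circular layout of
#' the merged DAG with the standard colour code: green and red nodes are the
#' name- and structure-matched classes, orange the non-matched contribution
#' of A, blue the classes appended from B. Node labels appear as hover
#' titles. Every number shown is taken from the same statistics list that is
#' serialised to the JSON file. Graphs larger than `nodeCap` are summarised
#' without a drawing.
#'
#' @param res a [MergeResult-class].
#' @param al the [Alignment-class] that produced it.
#' @param path output HTML path.
#' @param stats statistics list from [mergeStats()]; recomputed if missing.
#' @param nodeCap largest graph drawn (default 500 nodes).
#' @return `path`, invisibly.
#' @export
renderReport <- function(res, al, path, stats = NULL, nodeCap = 500L) {
  stopifnot(is(res, "MergeResult"), is(al, "Alignment"))
  if (is.null(stats)) stats <- mergeStats(res)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  rows <- vapply(names(stats), function(k) {
    v <- stats[[k]]
    sprintf("<tr><td>%s</td><td>%s</td></tr>", esc(gsub("_", " ", k)),
            if (is.null(v) || length(v) == 0 || is.na(v)) "-" else
              format(v, nsmall = 0))
  }, character(1))
  donut <- .donutSvg(stats)
  dag <- if (nrow(res@merged@classes) <= nodeCap) {
    .circularDagSvg(res, al)
  } else {
    sprintf("<p class='notice'>Graph with %d classes exceeds the %d-node drawing cap; summary only.</p>",
            nrow(res@merged@classes), nodeCap)
  }
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'><title>Ontology merge report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td{border:1px solid #999;padding:2px 8px}h2{margin-top:1.4em}",
    ".legend span{margin-right:1.2em}.notice{color:#a33}</style></head><body>",
    sprintf("<h1>Merge report: %s</h1>", esc(res@merged@name)),
    "<h2>Statistics</h2>", "<table>", rows, "</table>",
    "<h2>Match breakdown</h2>", donut,
    "<h2>Merged ontology (circular layout)</h2>",
    paste0("<p class='legend'>",
           "<span style='color:#2a2'>&#9679; name match</span>",
           "<span style='color:#c22'>&#9679; structure match</span>",
           "<span style='color:#e80'>&#9679; non-matched (A)</span>",
           "<span style='color:#26c'>&#9679; added from B</span></p>"),
    dag,
    "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

# donut of name/structure/non-matched counts over the classes of A
.donutSvg <- function(stats) {
  counts <- c(name = stats$n_name_matches,
              structure = stats$n_structure_matches,
              none = stats$n_classes_A - stats$n_name_matches -
                     stats$n_structure_matches)
  cols <- c(name = "#2a2", structure = "#c22", none = "#bbb")
  total <- sum(counts)
  if (total == 0) return("<p>No classes to summarise.</p>")
  cx <- 110; cy <- 110; r1 <- 55; r2 <- 100
  a0 <- -pi / 2
  paths <- character(0)
  for (k in names(counts)) {
    if (counts[[k]] == 0) next
    a1 <- a0 + 2 * pi * counts[[k]] / total
    paths <- c(paths, .arcPath(cx, cy, r1, r2, a0, a1, cols[[k]],
                               sprintf("%s: %d", k, counts[[k]])))
    a0 <- a1
  }
  c(sprintf("<svg width='340' height='220' role='img'>"),
    paths,
    sprintf("<text x='%d' y='%d' text-anchor='middle' font-size='13'>%d classes</text>",
            cx, cy + 4, total),
    sprintf("<text x='240' y='60' font-size='12' fill='#2a2'>name: %s%%</text>",
            stats$pct_name_matches),
    sprintf("<text x='240' y='80' font-size='12' fill='#c22'>structure: %s%%</text>",
            stats$pct_structure_matches),
    sprintf("<text x='240' y='100' font-size='12' fill='#777'>non-matched: %s%%</text>",
            stats$pct_non_matched),
    "</svg>")
}

.arcPath <- function(cx, cy, r1, r2, a0, a1, fill, title) {
  if (a1 - a0 >= 2 * pi - 1e-9) a1 <- a0 + 2 * pi - 1e-6
  large <- as.integer((a1 - a0) > pi)
  p <- function(r, a) sprintf("%.2f %.2f", cx + r * cos(a), cy + r * sin(a))
  sprintf(paste0("<path d='M %s A %.2f %.2f 0 %d 1 %s L %s A %.2f %.2f 0 %d 0 %s Z' ",
                 "fill='%s'><title>%s</title></path>"),
          p(r2, a0), r2, r2, large, p(r2, a1),
          p(r1, a1), r1, r1, large, p(r1, a0), fill, title)
}

.circularDagSvg <- function(res, al) {
  onto <- res@merged
  ids <- onto@classes$id
  n <- length(ids)
  labels <- classLabels(onto)
  rec <- al@records
  colour <- structure(rep("#e80", n), names = ids)  # A non-matched
  colour[rec$nativeId[rec$matchType == "Name"]] <- "#2a2"
  colour[rec$nativeId[rec$matchType == "Structure"]] <- "#c22"
  colour[names(res@provenance)[res@provenance == "B"]] <- "#26c"
  size <- 640
  cx <- size / 2; cy <- size / 2; r <- size / 2 - 30
  ang <- 2 * pi * (seq_len(n) - 1) / n - pi / 2
  x <- cx + r * cos(ang)
  y <- cy + r * sin(ang)
  names(ang) <- ids
  px <- structure(x, names = ids)
  py <- structure(y, names = ids)
  edges <- onto@edges
  lines <- if (nrow(edges) > 0) {
    sprintf("<line x1='%.1f' y1='%.1f' x2='%.1f' y2='%.1f' stroke='#ccc' stroke-width='0.5'/>",
            px[edges[, 1]], py[edges[, 1]], px[edges[, 2]], py[edges[, 2]])
  } else character(0)
  nodes <- sprintf("<circle cx='%.1f' cy='%.1f' r='3' fill='%s'><title>%s</title></circle>",
                   px[ids], py[ids], colour[ids],
                   vapply(unname(labels[ids]), function(s) {
                     s <- gsub("&", "&amp;", s, fixed = TRUE)
                     gsub("<", "&lt;", s, fixed = TRUE)
                   }, character(1)))
  c(sprintf("<svg width='%d' height='%d' role='img'>", size, size),
    lines, nodes, "</svg>")
}
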