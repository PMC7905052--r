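#' Run the full fusion pipeline on two ontologies
#'
#' Orchestrates the stages in order: optional edit scripts (automatic
#' ontology editor), name mapping matrix, structure mapping matrix over the
#' name-unmatched generators, alignment cascade, and merging of B into A.
#' Stage sizes and elapsed times are logged as messages when `verbose`.
#'
#' @param A,B [OntologyGraph-class] objects.
#' @param cfg a [FusionConfig-class].
#' @param editA,editB optional `"EditScript"` objects applied to A and B
#'   before alignment.
#' @param verbose log per-stage progress.
#' @return A list of class `"FusionRun"`: the (possibly edited) inputs
#'   `ontoA`/`ontoB`, the name matrix `S`, structure matrix `Tm`, the
#'   `alignment`, the `merge` result and the `stats` list from
#'   [mergeStats()].
#' @examples
#' pair <- deriveVariant(generateBaseOntology(40, seed = 7),
#'                       labelEditRate = 0.1, seed = 7)
#' run <- fuseOntologies(ontologyA(pair), ontologyB(pair))
#' run$stats$n_name_matches
#' @export
fuseOntologies <- function(A, B, cfg = fusionConfig(), editA = NULL,
                           editB = NULL, verbose = FALSE) {
  stopifnot(is(A, "OntologyGraph"), is(B, "OntologyGraph"),
            is(cfg, "FusionConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    say("[%s] done in %.2fs", what, proc.time()[["elapsed"]] - t0)
    out
  }
  if (!is.null(editA))
    A <- stage("preprocess A", applyEditScript(A, editA))
  if (!is.null(editB))
    B <- stage("preprocess B", applyEditScript(B, editB))
  say("inputs: A %d classes / %d relations; B %d classes / %d relations",
      nClasses(A), nEdges(A), nClasses(B), nEdges(B))
  S <- stage("name matrix", buildNameMatrix(A, B, cfg))
  Tm <- stage("structure matrix", buildStructureMatrix(A, B, S, cfg))
  say("structure matrix: %d x %d generators", nrow(Tm), ncol(Tm))
  al <- stage("alignment", alignOntologies(A, B, S, Tm, cfg))
  mg <- stage("merge", mergeOntologies(A, B, al))
  stats <- mergeStats(mg, nA = nClasses(A), nB = nClasses(B),
                      nRelA = nEdges(A))
  structure(list(ontoA = A, ontoB = B, S = S, Tm = Tm, alignment = al,
                 merge = mg, stats = stats, config = cfg),
            class = "FusionRun")
}

#' @export
print.FusionRun <- function(x, ...) {
  cat("FusionRun\n")
  show(x$alignment)
  show(x$merge)
  invisible(x)
}
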