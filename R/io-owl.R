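.owlNs <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  oboInOwl = "http://www.geneontology.org/formats/oboInOwl#"
)

#' Read an ontology from an OWL (RDF/XML) file
#'
#' Reads the class-declaration subset of OWL: named `owl:Class` elements
#' with `rdfs:label` annotations, exact-synonym annotation properties and
#' `rdfs:subClassOf` axioms between named classes. A subclass axiom is
#' oriented parent-to-child. Anonymous and restriction superclasses are
#' ignored (their count is reported as a message); classes referenced in a
#' subclass axiom but never declared are auto-created with the id fragment
#' as label, with a warning; duplicated axioms collapse to one edge. A class
#' without a label gets its id fragment (the part after `#` or the last `/`)
#' as label.
#'
#' @param path path to the .owl file.
#' @param synonymProps local names of the annotation properties read as
#'   synonyms (the oboInOwl exact-synonym property by default).
#' @param name ontology identifier; defaults to the file name.
#' @return An [OntologyGraph-class].
#' @export
readOWL <- function(path, synonymProps = c("hasExactSynonym"),
                    name = basename(path)) {
  if (!file.exists(path)) stop("OWL file not found: ", path)
  doc <- xml2::read_xml(path)
  classes <- xml2::xml_find_all(
    doc, "//owl:Class[@rdf:about | @rdf:ID]", ns = .owlNs)
  ids <- character(0)
  labels <- character(0)
  synonyms <- list()
  edges <- NULL
  nAnonymous <- 0L
  for (cls in classes) {
    id <- xml2::xml_attr(cls, "rdf:about", ns = .owlNs)
    if (is.na(id)) id <- xml2::xml_attr(cls, "rdf:ID", ns = .owlNs)
    id <- utils::URLdecode(id)
    if (id %in% ids) next  # duplicate declaration: first one wins
    lab <- xml2::xml_text(
      xml2::xml_find_first(cls, "./rdfs:label", ns = .owlNs))
    if (is.na(lab) || !nzchar(lab)) lab <- .idFragment(id)
    synSel <- paste(sprintf("./oboInOwl:%s | ./*[local-name()='%s']",
                            synonymProps, synonymProps), collapse = " | ")
    syns <- unique(xml2::xml_text(
      xml2::xml_find_all(cls, synSel, ns = .owlNs)))
    parents <- xml2::xml_find_all(cls, "./rdfs:subClassOf", ns = .owlNs)
    for (p in parents) {
      res <- xml2::xml_attr(p, "rdf:resource", ns = .owlNs)
      if (is.na(res)) {
        nAnonymous <- nAnonymous + 1L  # anonymous/restriction superclass
      } else {
        edges <- rbind(edges, c(utils::URLdecode(res), id))
      }
    }
    ids <- c(ids, id)
    labels <- c(labels, lab)
    synonyms[[id]] <- syns
  }
  if (nAnonymous > 0)
    message(nAnonymous, " anonymous/restriction superclass(es) ignored")
  undeclared <- setdiff(unique(as.vector(edges)), ids)
  if (length(undeclared)) {
    warning(length(undeclared),
            " class(es) referenced but never declared; auto-created: ",
            paste(head(undeclared, 3), collapse = ", "))
    ids <- c(ids, undeclared)
    labels <- c(labels, vapply(undeclared, .idFragment, ""))
  }
  suppressMessages(
    ontologyGraph(ids, labels, edges = edges, synonyms = synonyms,
                  name = name))
}

.idFragment <- function(id) {
  frag <- sub("^.*#", "", id)
  if (identical(frag, id)) frag <- sub("^.*/", "", id)
  frag
}

#' Write an ontology to an OWL (RDF/XML) file
#'
#' Emits one `owl:Class` per class with its `rdfs:label`, one exact-synonym
#' annotation per synonym and one `rdfs:subClassOf` axiom per parent. When a
#' provenance map is given, classes appended from ontology B (provenance
#' `"B"`) are written at the start of the class block. Ids are URL-encoded
#' in `rdf:about`, so [readOWL()] of the output reconstructs the graph
#' exactly (same ids, labels, synonyms and edges).
#'
#' @param onto an [OntologyGraph-class].
#' @param path output file path.
#' @param provenance optional named character vector (ids to
#'   `"A"`/`"B"`/`"both"`) as produced by [mergeOntologies()].
#' @return `path`, invisibly.
#' @export
writeOWL <- function(onto, path, provenance = NULL) {
  stopifnot(is(onto, "OntologyGraph"))
  ids <- onto@classes$id
  if (!is.null(provenance)) {
    newB <- ids[ids %in% names(provenance)[provenance == "B"]]
    ids <- c(newB, setdiff(ids, newB))
  }
  labels <- classLabels(onto)
  parents <- split(onto@edges[, 1], onto@edges[, 2])
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, useBytes = TRUE)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w(paste0('<rdf:RDF xmlns:rdf="%s"\n         xmlns:rdfs="%s"',
           '\n         xmlns:owl="%s"\n         xmlns:oboInOwl="%s">'),
    .owlNs["rdf"], .owlNs["rdfs"], .owlNs["owl"], .owlNs["oboInOwl"])
  w('  <owl:Ontology rdf:about="%s"/>', esc(utils::URLencode(onto@name)))
  for (id in ids) {
    w('  <owl:Class rdf:about="%s">', esc(utils::URLencode(id, reserved = TRUE)))
    w('    <rdfs:label>%s</rdfs:label>', esc(labels[[id]]))
    for (s in onto@synonyms[[id]])
      w('    <oboInOwl:hasExactSynonym>%s</oboInOwl:hasExactSynonym>', esc(s))
    for (p in parents[[id]])
      w('    <rdfs:subClassOf rdf:resource="%s"/>',
        esc(utils::URLencode(p, reserved = TRUE)))
    w('  </owl:Class>')
  }
  w('</rdf:RDF>')
  invisible(path)
}
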