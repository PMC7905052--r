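#' Built-in vocabulary for synthetic cell-ontology labels
#'
#' Words used to assemble synthetic class labels (2-4 word phrases). The
#' list mixes anatomical, developmental and cell-biology terms so that
#' generated labels resemble cell-type names without cloning any real
#' ontology's label distribution.
#'
#' @return Character vector of lowercase words.
#' @export
cellVocabulary <- function() {
  c("neural", "crest", "epithelial", "mesenchymal", "hematopoietic",
    "progenitor", "precursor", "stem", "basal", "luminal", "cortical",
    "medullary", "dorsal", "ventral", "lateral", "proximal", "distal",
    "embryonic", "fetal", "adult", "primordial", "committed", "transient",
    "amplifying", "ciliated", "secretory", "goblet", "club", "alveolar",
    "bronchial", "hepatic", "pancreatic", "endocrine", "exocrine", "islet",
    "ductal", "acinar", "cardiac", "smooth", "skeletal", "muscle",
    "satellite", "endothelial", "pericyte", "fibroblast", "myofibroblast",
    "osteoblast", "osteoclast", "chondrocyte", "adipocyte", "keratinocyte",
    "melanocyte", "neuron", "astrocyte", "oligodendrocyte", "microglial",
    "radial", "glial", "retinal", "photoreceptor", "bipolar", "ganglion",
    "erythroid", "myeloid", "lymphoid", "megakaryocyte", "monocyte",
    "macrophage", "dendritic", "plasma", "memory", "naive", "effector",
    "germinal", "trophoblast", "amniotic", "yolk", "sac", "endoderm",
    "mesoderm", "ectoderm", "epiblast", "hypoblast", "notochord", "somite")
}

#' Generate a synthetic base ontology
#'
#' Builds a rooted DAG of `n` classes: a breadth-first tree whose child
#' counts are Poisson with the given mean, plus a fraction of extra
#' downward edges that create multi-parent classes while preserving
#' acyclicity. Labels are unique 2-4 word phrases sampled from the
#' vocabulary; a stated fraction of classes receive 1-2 synonyms (word
#' permutations or fresh phrases). With the defaults the class/relation
#' shape mirrors a mid-sized curated cell ontology (about 1.15 relations
#' per class). Fully determined by `seed`.
#'
#' @param n number of classes (>= 1).
#' @param branchingMean mean child count of the tree layer.
#' @param vocabulary word list for labels.
#' @param synonymFraction fraction of classes given synonyms.
#' @param extraEdgeFraction extra DAG edges as a fraction of `n`.
#' @param seed integer seed; the same seed reproduces the graph exactly.
#' @param name ontology identifier.
#' @return An [OntologyGraph-class].
#' @export
generateBaseOntology <- function(n, branchingMean = 1.15,
                                 vocabulary = cellVocabulary(),
                                 synonymFraction = 0.3,
                                 extraEdgeFraction = 0.15,
                                 seed = 1L, name = "synthetic") {
  if (n < 1) stop("n must be >= 1")
  withr::with_seed(as.integer(seed), {
    parent <- integer(n)  # 0 for the root
    depth <- integer(n)
    queue <- 1L
    created <- 1L
    while (created < n) {
      if (length(queue) == 0) {
        p <- sample.int(created, 1L)
        k <- 1L
      } else {
        p <- queue[1L]
        queue <- queue[-1L]
        k <- stats::rpois(1L, branchingMean)
      }
      k <- min(k, n - created)
      if (k > 0) {
        kids <- created + seq_len(k)
        parent[kids] <- p
        depth[kids] <- depth[p] + 1L
        queue <- c(queue, kids)
        created <- created + k
      }
    }
    ids <- sprintf("C%04d", seq_len(n))
    edges <- if (n > 1) cbind(ids[parent[-1L]], ids[-1L]) else NULL
    # extra strictly-downward edges keep the graph acyclic
    mExtra <- round(extraEdgeFraction * n)
    if (mExtra > 0 && n > 2) {
      have <- if (is.null(edges)) character(0) else
        paste(edges[, 1], edges[, 2], sep = "\r")
      added <- 0L
      attempts <- 0L
      while (added < mExtra && attempts < 20L * mExtra) {
        attempts <- attempts + 1L
        u <- sample.int(n, 1L)
        v <- sample.int(n, 1L)
        if (depth[u] >= depth[v]) next
        key <- paste(ids[u], ids[v], sep = "\r")
        if (key %in% have) next
        edges <- rbind(edges, c(ids[u], ids[v]))
        have <- c(have, key)
        added <- added + 1L
      }
    }
    labels <- .samplePhrases(n, vocabulary, avoid = character(0))
    synonyms <- list()
    withSyn <- which(stats::runif(n) < synonymFraction)
    for (i in withSyn) {
      k <- sample(1:2, 1L)
      syns <- character(0)
      for (. in seq_len(k)) {
        s <- if (stats::runif(1) < 0.5) .permutePhrase(labels[i])
             else .onePhrase(vocabulary)
        if (s != labels[i]) syns <- c(syns, s)
      }
      if (length(syns)) synonyms[[ids[i]]] <- unique(syns)
    }
    ontologyGraph(ids, labels, edges = edges, synonyms = synonyms,
                  name = name)
  })
}

.onePhrase <- function(vocabulary) {
  paste(sample(vocabulary, sample(2:4, 1L)), collapse = " ")
}

.permutePhrase <- function(phrase) {
  w <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  paste(sample(w), collapse = " ")
}

.samplePhrases <- function(n, vocabulary, avoid) {
  out <- character(n)
  seen <- avoid
  for (i in seq_len(n)) {
    p <- .onePhrase(vocabulary)
    tries <- 0L
    while (p %in% seen && tries < 25L) {
      p <- .onePhrase(vocabulary)
      tries <- tries + 1L
    }
    if (p %in% seen) p <- paste(p, "type", i)
    out[i] <- p
    seen <- c(seen, p)
  }
  out
}

#' Derive a perturbed variant with known correspondences
#'
#' Produces ontology B from a base ontology A by: dropping classes (their
#' parents are rewired to their children), per-character label edits at the
#' stated rate (substitutions, insertions and deletions of word-internal
#' letters, so token structure persists), swapping labels with synonyms,
#' and grafting novel subtrees of a few classes each. The ground truth maps
#' every surviving base class to itself; dropped and grafted classes never
#' appear in it. Fully determined by `seed`.
#'
#' At the default edit rate of 0.13 the expected scaled name similarity
#' between a label and its edited copy is about 0.9 for the 2-4 word labels
#' of [generateBaseOntology()] (about 16 editable word-internal letters in
#' a 21-character label).
#'
#' @param base the base [OntologyGraph-class].
#' @param labelEditRate per word-internal-character edit probability in
#'   \[0,1\].
#' @param nClassDrops classes to drop (must stay below the class count).
#' @param nSubtreeGrafts novel subtrees (2-6 classes each) to graft.
#' @param synonymSwapRate probability of swapping a class label with its
#'   first synonym.
#' @param seed integer seed.
#' @return A [SyntheticPair-class].
#' @export
deriveVariant <- function(base, labelEditRate = 0.13, nClassDrops = 0L,
                          nSubtreeGrafts = 0L, synonymSwapRate = 0L,
                          seed = 1L) {
  stopifnot(is(base, "OntologyGraph"))
  if (labelEditRate < 0 || labelEditRate > 1 ||
      synonymSwapRate < 0 || synonymSwapRate > 1)
    stop("rates must lie in [0, 1]")
  if (nClassDrops >= nClasses(base))
    stop("cannot drop ", nClassDrops, " of ", nClasses(base), " classes")
  withr::with_seed(as.integer(seed) + 1L, {
    cl <- base@classes
    syn <- base@synonyms
    edges <- base@edges
    ids <- cl$id

    if (nClassDrops > 0) {
      hasParent <- ids %in% edges[, 2]
      droppable <- ids[hasParent]  # keep roots
      drops <- sample(droppable, min(nClassDrops, length(droppable)))
      for (d in drops) {
        ps <- edges[edges[, 2] == d, 1]
        cs <- edges[edges[, 1] == d, 2]
        edges <- edges[edges[, 1] != d & edges[, 2] != d, , drop = FALSE]
        if (length(ps) && length(cs)) {
          grid <- expand.grid(parent = ps, child = cs,
                              stringsAsFactors = FALSE)
          edges <- rbind(edges, as.matrix(grid))
        }
      }
      edges <- edges[!duplicated(paste(edges[, 1], edges[, 2], sep = "\r")),
                     , drop = FALSE]
      keep <- !(ids %in% drops)
      cl <- cl[keep, , drop = FALSE]
      syn <- syn[cl$id]
      ids <- cl$id
    }

    truthIds <- ids

    if (synonymSwapRate > 0) {
      for (i in seq_along(ids)) {
        s <- syn[[ids[i]]]
        if (length(s) > 0 && stats::runif(1) < synonymSwapRate) {
          old <- cl$label[i]
          cl$label[i] <- s[1L]
          syn[[ids[i]]] <- unique(c(old, s[-1L]))
        }
      }
    }

    if (labelEditRate > 0)
      cl$label <- vapply(cl$label, .editLabel, "", rate = labelEditRate,
                         USE.NAMES = FALSE)

    if (nSubtreeGrafts > 0) {
      gCount <- 0L
      for (g in seq_len(nSubtreeGrafts)) {
        size <- stats::rpois(1L, 3L) + 2L
        gIds <- sprintf("G%03d", gCount + seq_len(size))
        gCount <- gCount + size
        gLabels <- .samplePhrases(size, cellVocabulary(), avoid = cl$label)
        anchor <- sample(ids, 1L)
        gParent <- c(anchor, gIds[pmax(1L, ceiling(seq_len(size - 1L) / 2L))])
        gEdges <- cbind(gParent, c(gIds[1L], gIds[-1L]))
        cl <- rbind(cl, data.frame(id = gIds, label = gLabels,
                                   stringsAsFactors = FALSE))
        edges <- rbind(edges, gEdges)
      }
      ids <- cl$id
    }

    ontoB <- ontologyGraph(cl$id, cl$label, edges = edges, synonyms = syn,
                           name = paste0(base@name, "-variant"))
    new("SyntheticPair",
        ontoA = base, ontoB = ontoB,
        truth = data.frame(aId = truthIds, bId = truthIds,
                           stringsAsFactors = FALSE),
        params = list(labelEditRate = labelEditRate,
                      nClassDrops = nClassDrops,
                      nSubtreeGrafts = nSubtreeGrafts,
                      synonymSwapRate = synonymSwapRate,
                      seed = as.integer(seed)))
  })
}

# per-character edits on word-internal letters: substitution (60%),
# insertion (20%), deletion (20%)
.editLabel <- function(label, rate) {
  chars <- strsplit(label, "")[[1]]
  out <- character(0)
  prevLetter <- FALSE
  for (ch in chars) {
    isLetter <- grepl("[a-z]", ch)
    if (isLetter && prevLetter && stats::runif(1) < rate) {
      kind <- sample(c("sub", "ins", "del"), 1L, prob = c(0.6, 0.2, 0.2))
      if (kind == "sub") {
        out <- c(out, sample(setdiff(letters, ch), 1L))
      } else if (kind == "ins") {
        out <- c(out, ch, sample(letters, 1L))
      }  # del: drop the character
    } else {
      out <- c(out, ch)
    }
    prevLetter <- isLetter
  }
  res <- paste(out, collapse = "")
  if (nzchar(trimws(res))) res else label
}

#' Accessors for SyntheticPair objects
#'
#' @param x a [SyntheticPair-class].
#' @name SyntheticPair-accessors
NULL

#' @rdname SyntheticPair-accessors
#' @export
setMethod("ontologyA", "SyntheticPair", function(x) x@ontoA)

#' @rdname SyntheticPair-accessors
#' @export
setMethod("ontologyB", "SyntheticPair", function(x) x@ontoB)

#' @rdname SyntheticPair-accessors
#' @export
setMethod("truthPairs", "SyntheticPair", function(x) x@truth)

setMethod("show", "SyntheticPair", function(object) {
  cat(sprintf("SyntheticPair: A %d classes, B %d classes, %d truth pairs\n",
              nClasses(object@ontoA), nClasses(object@ontoB),
              nrow(object@truth)))
})

#' The study-condition synthetic pair
#'
#' One call producing the standard evaluation condition of the package's
#' simulation study: a 300-class base ontology with Poisson(1.15) branching,
#' a variant with word-internal label edits at rate 0.13 (expected scaled
#' name similarity about 0.9) and six grafted subtrees (about 10% novel
#' classes), no drops, no synonym swaps.
#'
#' @param seed integer seed.
#' @return A [SyntheticPair-class].
#' @export
studyPair <- function(seed) {
  base <- generateBaseOntology(300L, branchingMean = 1.15,
                               seed = as.integer(seed),
                               name = sprintf("study-%d", seed))
  deriveVariant(base, labelEditRate = 0.13, nClassDrops = 0L,
                nSubtreeGrafts = 6L, synonymSwapRate = 0,
                seed = as.integer(seed))
}
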