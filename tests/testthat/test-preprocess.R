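test_that("label normalisation strips, drops stop words and is idempotent", {
  expect_equal(normalizeLabel("Hypoblast Cells",
                              stopWords = c("cell", "cells")), "hypoblast")
  expect_equal(normalizeLabel("yolk-sac/endoderm",
                              stripChars = c("-", "/")), "yolk sac endoderm")
  expect_equal(normalizeLabel(""), "")
  # whole-token removal leaves words containing the stop word intact
  expect_equal(normalizeLabel("cellular matrix cell",
                              stopWords = "cell"), "cellular matrix")
  strip <- c("-", "/", ",")
  sw <- c("cell", "cells", "human")
  labs <- c("Embryonic Stem Cells, human", "neural-crest/progenitor",
            "  spaced   out  ", "CELL", "-/,")
  once <- normalizeLabel(labs, strip, sw)
  expect_identical(normalizeLabel(once, strip, sw), once)
})

test_that("deselect removes matching classes with their incident edges", {
  g <- ontologyGraph(c("r", "i", "k"),
                     c("root", "immune cell", "killer"),
                     edges = rbind(c("r", "i"), c("i", "k")))
  out <- applyEditScript(g, editScript(list(op = "deselect",
                                            pattern = "immune cell")))
  expect_setequal(classIds(out), c("r", "k"))
  expect_equal(nEdges(out), 0)
  # everything else intact
  expect_identical(classLabels(out)[["k"]], "killer")
})

test_that("select keeps matches (labels or synonyms) and empty script is identity", {
  g <- ontologyGraph(c("a", "b", "c"), c("stem", "neuron", "muscle"),
                     synonyms = list(c = "stemlike"),
                     edges = rbind(c("a", "b"), c("a", "c")))
  out <- applyEditScript(g, editScript(list(op = "select", pattern = "stem")))
  expect_setequal(classIds(out), c("a", "c"))  # synonym matched too
  expect_identical(applyEditScript(g, editScript()), g)
  expect_warning(
    empty <- applyEditScript(g, editScript(list(op = "select",
                                                pattern = "zzz"))),
    "matched no class")
  expect_equal(nClasses(empty), 0)
  # select then deselect with the same pattern empties the ontology
  out2 <- applyEditScript(g, editScript(
    list(op = "select", pattern = "stem"),
    list(op = "deselect", pattern = "stem")))
  expect_equal(nClasses(out2), 0)
})

test_that("connect adds one edge and errors on absent classes", {
  g <- ontologyGraph(c("a", "b"), c("alpha", "beta"))
  out <- applyEditScript(g, editScript(
    list(op = "connect", parent = "alpha", child = "beta")))
  expect_identical(unname(edgeTable(out)), rbind(c("a", "b")))
  expect_error(applyEditScript(g, editScript(
    list(op = "connect", parent = "alpha", child = "nope"))),
    "absent.*nope")
})

test_that("merge_classes unions edges and synonyms, absorbed label becomes a synonym", {
  g <- ontologyGraph(c("h", "m", "p", "q"),
                     c("human X", "mouse X", "parent", "child"),
                     synonyms = list(m = "murine X"),
                     edges = rbind(c("p", "h"), c("p", "m"), c("m", "q"),
                                   c("h", "m")))
  out <- applyEditScript(g, editScript(
    list(op = "merge_classes", keep = "human X", absorb = "mouse X")))
  expect_setequal(classIds(out), c("h", "p", "q"))
  # union of edges, relabelled to the kept id, self-loop (h->m) removed
  expect_setequal(paste(edgeTable(out)[, 1], edgeTable(out)[, 2]),
                  c("p h", "h q"))
  expect_setequal(classSynonyms(out, "h"), c("mouse X", "murine X"))
  expect_error(applyEditScript(g, editScript(
    list(op = "merge_classes", keep = "human X", absorb = "gone"))),
    "absent.*gone")
})

test_that("normalize_labels is applied to labels and synonyms, empties kept", {
  g <- ontologyGraph(c("a", "b"), c("Stem Cells", "cell"),
                     synonyms = list(a = c("Stem-Cell")))
  expect_warning(
    out <- applyEditScript(g, editScript(
      list(op = "normalize_labels", stripChars = "-",
           stopWords = c("cell", "cells")))),
    "kept unchanged")
  expect_identical(classLabels(out)[["a"]], "stem")
  expect_identical(classLabels(out)[["b"]], "cell")  # would be empty
  expect_identical(classSynonyms(out, "a"), character(0))  # "stem" == label
})

test_that("edited ontologies never hold dangling, duplicate or loop edges", {
  for (seed in 1:5) {
    g <- randomDag(15, 0.2, seed)
    labs <- classLabels(g)
    out <- applyEditScript(g, editScript(
      list(op = "deselect", pattern = substr(labs[[3]], 1, 3)),
      list(op = "normalize_labels", stripChars = "0",
           stopWords = character())))
    e <- edgeTable(out)
    expect_true(all(e %in% classIds(out)))
    expect_false(any(e[, 1] == e[, 2]))
    expect_false(anyDuplicated(paste(e[, 1], e[, 2])) > 0)
    expect_true(validObject(out))
  }
})
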