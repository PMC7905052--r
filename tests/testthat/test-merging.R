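sameOntologyContent <- function(x, y) {
  identical(sort(classIds(x)), sort(classIds(y))) &&
    identical(classLabels(x)[sort(classIds(x))],
              classLabels(y)[sort(classIds(y))]) &&
    setequal(paste(edgeTable(x)[, 1], edgeTable(x)[, 2]),
             paste(edgeTable(y)[, 1], edgeTable(y)[, 2])) &&
    all(vapply(classIds(x), function(id) {
      setequal(classSynonyms(x, id), classSynonyms(y, id))
    }, logical(1)))
}

test_that("self-merge is the identity with zero additions", {
  g <- generateBaseOntology(30, seed = 6)
  run <- fuseOntologies(g, g)
  res <- run$merge
  expect_equal(res@nAddedClasses, 0L)
  expect_equal(res@nAddedRelations, 0L)
  expect_equal(res@nNameMatches, nClasses(g))
  expect_true(sameOntologyContent(mergedOntology(res), g))
  st <- mergeStats(res)
  expect_equal(st$pct_name_matches, 100)
  expect_equal(st$pct_added_classes, 0)
})

test_that("a matched class gains its partner's offspring relation", {
  A <- ontologyGraph(c("a", "b"), c("alpha", "beta"), edges = cbind("a", "b"))
  B <- ontologyGraph(c("a2", "c2"), c("alpha", "gamma"),
                     edges = cbind("a2", "c2"))
  run <- fuseOntologies(A, B)
  res <- run$merge
  m <- mergedOntology(res)
  expect_equal(nClasses(m), 3)
  expect_equal(res@nAddedClasses, 1L)
  expect_equal(res@nAddedRelations, 1L)
  labs <- unname(sort(classLabels(m)))
  expect_identical(labs, c("alpha", "beta", "gamma"))
  # the new gamma class hangs under the unified alpha class
  e <- edgeTable(m)
  expect_setequal(e[, 1], "a")
  expect_equal(nrow(e), 2)
})

test_that("disjoint ontologies concatenate completely", {
  A <- generateBaseOntology(15, seed = 25)
  B <- ontologyGraph(sprintf("q%02d", 1:10), sprintf("zz %02d qqq", 1:10),
                     edges = cbind("q01", sprintf("q%02d", 2:10)))
  run <- fuseOntologies(A, B)
  expect_equal(nClasses(mergedOntology(run$merge)), 25)
  expect_equal(run$merge@nMatchedB, 0L)
  expect_equal(mergeStats(run$merge)$pct_name_matches, 0)
})

test_that("class-count conservation holds across random pairs", {
  for (seed in 1:6) {
    pair <- deriveVariant(generateBaseOntology(20 + 4 * seed, seed = seed),
                          labelEditRate = 0.2, nClassDrops = seed %% 3,
                          nSubtreeGrafts = seed %% 2, seed = seed)
    A <- ontologyA(pair)
    B <- ontologyB(pair)
    run <- fuseOntologies(A, B)
    expect_equal(nClasses(mergedOntology(run$merge)),
                 nClasses(A) + nClasses(B) - run$merge@nMatchedB)
    e <- edgeTable(mergedOntology(run$merge))
    expect_false(anyDuplicated(paste(e[, 1], e[, 2])) > 0)
    expect_true(all(paste(edgeTable(A)[, 1], edgeTable(A)[, 2]) %in%
                      paste(e[, 1], e[, 2])))
  }
})

test_that("merging reaches a fixpoint at fixed thresholds", {
  pair <- deriveVariant(generateBaseOntology(25, seed = 33),
                        labelEditRate = 0.1, nSubtreeGrafts = 1, seed = 33)
  run1 <- fuseOntologies(ontologyA(pair), ontologyB(pair))
  merged <- mergedOntology(run1$merge)
  run2 <- fuseOntologies(merged, ontologyB(pair))
  expect_equal(run2$merge@nAddedClasses, 0L)
  expect_equal(run2$merge@nAddedRelations, 0L)
})

test_that("one B class matched by many A classes attaches to the best partner", {
  A <- ontologyGraph(c("a1", "a2"), c("stem cell", "stem cell x"))
  B <- ontologyGraph(c("b", "k"), c("stem cell", "offspring zz"),
                     edges = cbind("b", "k"))
  run <- fuseOntologies(A, B, fusionConfig(thetaN = 0.8))
  mp <- matchedPairs(run$alignment)
  expect_equal(nrow(mp), 2)          # both A classes match b
  m <- mergedOntology(run$merge)
  e <- edgeTable(m)
  # the offspring edge lands on the exact-match partner a1 only
  expect_equal(nrow(e), 1)
  expect_equal(unname(e[1, 1]), "a1")
  expect_equal(run$merge@nSynonymPairs, 2L)
  expect_equal(run$merge@nMatchedB, 1L)
})

test_that("merge statistics break matches down by type", {
  # 3 name + 1 structure matches of 10 B classes
  res <- new("MergeResult",
             merged = generateBaseOntology(12, seed = 1),
             nNameMatches = 3L, nStructureMatches = 1L, nMatchedB = 4L,
             nSynonymPairs = 4L, nAddedClasses = 6L, nAddedRelations = 2L,
             provenance = structure(
               c(rep("A", 2), rep("both", 4), rep("B", 6)),
               names = classIds(generateBaseOntology(12, seed = 1))))
  st <- mergeStats(res, nA = 10, nB = 10, nRelA = 20)
  expect_equal(st$pct_name_matches, 30)
  expect_equal(st$pct_structure_matches, 10)
  expect_equal(st$n_added_classes, 6L)
  expect_equal(st$pct_added_classes, 60)
  expect_equal(st$pct_added_relations, 10)
})
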