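test_that("identical ontologies align to themselves by name", {
  g <- generateBaseOntology(25, seed = 2)
  run <- fuseOntologies(g, g)
  rec <- alignmentRecords(run$alignment)
  expect_true(all(rec$matchType == "Name"))
  expect_identical(rec$translatedId, rec$nativeId)
  expect_true(all(rec$nameScore == 1))
})

test_that("zero evidence yields only non-matched records", {
  A <- ontologyGraph(c("a1", "a2"), c("one", "two"), edges = cbind("a1", "a2"))
  B <- ontologyGraph(c("b1", "b2"), c("three", "four"),
                     edges = cbind("b1", "b2"))
  S <- matrix(0, 2, 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
  Tm <- matrix(0, 2, 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
  al <- alignOntologies(A, B, S, Tm, fusionConfig())
  rec <- alignmentRecords(al)
  expect_true(all(rec$matchType == "Non-matched"))
  expect_true(all(rec$translatedLabel == ""))
  expect_equal(nrow(matchedPairs(al)), 0)
})

test_that("the cascade promotes a sub-threshold name pair via structure", {
  # S(i,j) = 0.80 < thetaN, T(i,j) = 0.9 >= thetaT, local mean 0.75 > thetaLN
  A <- ontologyGraph(c("x1", "x2"), c("alpha cell", "beta cell"),
                     edges = cbind("x1", "x2"))
  B <- ontologyGraph(c("y1", "y2"), c("alpho cell", "beta kell"),
                     edges = cbind("y1", "y2"))
  S <- matrix(0, 2, 2, dimnames = list(c("x1", "x2"), c("y1", "y2")))
  S["x1", "y1"] <- 0.80
  S["x2", "y2"] <- 0.70
  Tm <- matrix(0.9, 2, 2, dimnames = list(c("x1", "x2"), c("y1", "y2")))
  al <- alignOntologies(A, B, S, Tm, fusionConfig())
  rec <- alignmentRecords(al)
  # local mean for (x1,y1): members {x1,x2} vs {y1,y2}, best 0.80 and 0.70
  expect_identical(rec$matchType, c("Structure", "Structure"))
  expect_identical(rec$translatedId, c("y1", "y2"))
  expect_equal(rec$structureScore, c(0.9, 0.9))
  # raising thetaLN above the local mean blocks the confirmation
  al2 <- alignOntologies(A, B, S, Tm, fusionConfig(thetaLN = 0.76))
  expect_true(all(alignmentRecords(al2)$matchType == "Non-matched"))
  # raising thetaT above T blocks the candidate before confirmation
  al3 <- alignOntologies(A, B, S, Tm, fusionConfig(thetaT = 0.95))
  expect_true(all(alignmentRecords(al3)$matchType == "Non-matched"))
})

test_that("local name confirmation compares subgraph label sets", {
  g <- generateBaseOntology(12, seed = 4)
  S <- buildNameMatrix(g, g, fusionConfig())
  id <- classIds(g)[3]
  expect_true(localNameConfirm(g, g, id, id, S, fusionConfig()))
  # against completely alien labels the mean is far below any threshold
  h <- ontologyGraph(classIds(g), sprintf("zzzz%02d", seq_len(12)),
                     edges = edgeTable(g))
  S2 <- buildNameMatrix(g, h, fusionConfig())
  expect_false(localNameConfirm(g, h, id, id, S2, fusionConfig()))
})

test_that("several A classes may share one B partner", {
  A <- ontologyGraph(c("a1", "a2"), c("stem cell", "stem cell b"))
  B <- ontologyGraph("b1", "stem cell")
  S <- buildNameMatrix(A, B, fusionConfig())
  al <- alignOntologies(A, B, S,
                        matrix(numeric(), 0, 0), fusionConfig(thetaN = 0.8))
  mp <- matchedPairs(al)
  expect_equal(nrow(mp), 2)
  expect_true(all(mp$bId == "b1"))
})

test_that("thresholds act monotonically on match counts", {
  pair <- deriveVariant(generateBaseOntology(50, seed = 19),
                        labelEditRate = 0.15, nSubtreeGrafts = 2, seed = 19)
  A <- ontologyA(pair)
  B <- ontologyB(pair)
  S <- buildNameMatrix(A, B, fusionConfig())
  prevName <- Inf
  for (thN in seq(0.5, 0.95, by = 0.05)) {
    cfg <- fusionConfig(thetaN = thN)
    Tm <- buildStructureMatrix(A, B, S, cfg)
    al <- alignOntologies(A, B, S, Tm, cfg)
    n <- sum(alignmentRecords(al)$matchType == "Name")
    expect_lte(n, prevName)
    prevName <- n
  }
  cfg0 <- fusionConfig()
  Tm <- buildStructureMatrix(A, B, S, cfg0)
  prevStruct <- Inf
  for (thLN in seq(0.3, 0.9, by = 0.1)) {
    al <- alignOntologies(A, B, S, Tm, fusionConfig(thetaLN = thLN))
    n <- sum(alignmentRecords(al)$matchType == "Structure")
    expect_lte(n, prevStruct)
    prevStruct <- n
  }
})

test_that("the alignment table writes five columns and reads back", {
  pair <- deriveVariant(generateBaseOntology(20, seed = 23),
                        labelEditRate = 0.15, seed = 23)
  run <- fuseOntologies(ontologyA(pair), ontologyB(pair))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAlignmentTable(run$alignment, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_identical(names(back),
                   c("native_label", "translated_label", "name_score",
                     "structure_score", "match_type"))
  rec <- alignmentRecords(run$alignment)
  expect_equal(nrow(back), nrow(rec))
  expect_identical(table(back$match_type), table(rec$matchType))
  nm <- back$translated_label[back$match_type == "Non-matched"]
  expect_true(all(is.na(nm) | nm == ""))
  # scores are printed with 4 decimals
  expect_match(format(back$name_score[1], nsmall = 4), "^[01]\\.[0-9]{4}$")
})
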