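test_that("row convolution slides the shorter row with nc = |la-lb|+1", {
  expect_equal(rowConvolution(rep(1, 7), rep(1, 4))$nc, 4)
  for (m in c("cosine", "euclidean", "pearson")) {
    r <- rowConvolution(c(1, 0, 1), c(1, 0, 1), m)
    expect_equal(r$nc, 1)
    expect_equal(r$best, 1.0)
  }
  r <- rowConvolution(c(1, 0, 0, 1), 1, "cosine")
  expect_equal(r$nc, 4)
  expect_equal(r$best, 1.0)           # a slide lands on a 1
  expect_equal(r$scores, c(1, 0, 0, 1))
  expect_error(rowConvolution(numeric(0), 1), "non-empty")
})

test_that("per-slide scores stay in [0,1] and obey the nc law", {
  withr::with_seed(21, {
    for (i in 1:40) {
      la <- sample(1:12, 1)
      lb <- sample(1:12, 1)
      a <- stats::rbinom(la, 1, 0.4)
      b <- stats::rbinom(lb, 1, 0.4)
      for (m in c("cosine", "euclidean", "pearson")) {
        r <- rowConvolution(a, b, m)
        expect_equal(r$nc, abs(la - lb) + 1L)
        expect_length(r$scores, r$nc)
        expect_true(all(r$scores >= 0 & r$scores <= 1))
        expect_equal(r$best, max(r$scores))
      }
    }
  })
})

test_that("hand-checked slide scores for the three metrics", {
  # [1,1] against [1,0,1]: windows [1,0],[0,1] -> cosine 1/sqrt(2) twice
  r <- rowConvolution(c(1, 1), c(1, 0, 1), "cosine")
  expect_equal(r$scores, rep(1 / sqrt(2), 2))
  # euclidean: distances 1 and 1 over sqrt(2)
  r2 <- rowConvolution(c(1, 1), c(1, 0, 1), "euclidean")
  expect_equal(r2$scores, rep(1 - 1 / sqrt(2), 2))
  # pearson: [1,1] has zero variance; windows differ -> 0, identical -> 1
  r3 <- rowConvolution(c(1, 1), c(1, 0, 1), "pearson")
  expect_equal(r3$scores, c(0, 0))
  r4 <- rowConvolution(c(1, 0), c(1, 0, 1), "pearson")
  expect_equal(r4$scores, c(1, 0))    # anti-correlation clamps to 0
})

test_that("vectorial similarity is 1 on self, symmetric, label-blind", {
  chain <- chainOntology(6)
  sub <- extractSubgraph(chain, "c", 2)
  for (m in c("cosine", "euclidean", "pearson"))
    expect_equal(vectorialSimilarity(sub, sub, m), 1.0)

  g1 <- randomDag(10, 0.25, 31)
  g2 <- randomDag(10, 0.25, 32)
  s1 <- extractSubgraph(g1, classIds(g1)[2], 2)
  s2 <- extractSubgraph(g2, classIds(g2)[2], 2)
  for (m in c("cosine", "euclidean", "pearson")) {
    v <- vectorialSimilarity(s1, s2, m)
    expect_equal(v, vectorialSimilarity(s2, s1, m))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }

  # renaming classes while preserving structure leaves the score unchanged
  ren <- ontologyGraph(LETTERS[1:6],
                       edges = cbind(LETTERS[1:5], LETTERS[2:6]))
  subRen <- extractSubgraph(ren, "C", 2)
  expect_equal(vectorialSimilarity(sub, subRen, "cosine"),
               vectorialSimilarity(sub, sub, "cosine"))
})

test_that("constraint similarity weighs name matches by proximity", {
  # generator g with members at distances 1 and 3 on a chain, W = 4
  gA <- chainOntology(5, c("g", "k1", "x", "k3", "y"))
  gB <- chainOntology(4, c("h", "l1", "z", "l3"))
  subA <- extractSubgraph(gA, "g", 4)
  subB <- extractSubgraph(gB, "h", 4)
  mkS <- function(hits = NULL) {
    S <- matrix(0, 5, 4, dimnames = list(classIds(gA), classIds(gB)))
    if (!is.null(hits)) S[hits] <- 0.95
    S
  }
  # no name-matched pair: similarity 0
  expect_equal(constraintSimilarity(subA, subB, mkS(), 0.85, 4), 0)
  # matches at distances 1 and 3: C = (4+1-1) + (4+1-3) = 6; the smaller
  # subgraph has 4 members so the ceiling is (4-1)*4 = 12
  S2 <- mkS(rbind(c("k1", "l1"), c("k3", "l3")))
  expect_equal(constraintSimilarity(subA, subB, S2, 0.85, 4), 6 / 12)
  # a three-member opposite side caps the ceiling at (3-1)*4 = 8 -> 0.75
  gB3 <- chainOntology(3, c("h", "l1", "l3"))
  subB3 <- extractSubgraph(gB3, "h", 4)
  S3 <- matrix(0, 5, 3, dimnames = list(classIds(gA), classIds(gB3)))
  S3[cbind(c("k1", "k3"), c("l1", "l3"))] <- 0.9
  expect_equal(constraintSimilarity(subA, subB3, S3, 0.85, 4), 6 / 8)
  # adding a matched node never decreases the accumulated constraint
  S4 <- S3
  S4["x", "l1"] <- 0.9
  expect_gte(constraintSimilarity(subA, subB3, S4, 0.85, 4),
             constraintSimilarity(subA, subB3, S3, 0.85, 4))
})

test_that("Blondel similarity matches the Kronecker-power oracle", {
  expect_equal(blondelSimilarity(extractSubgraph(chainOntology(1), "a", 1),
                                 extractSubgraph(chainOntology(1), "a", 1)),
               1.0)
  withr::with_seed(41, {
    for (i in 1:20) {
      g1 <- randomDag(sample(3:8, 1), 0.35, sample.int(1e6, 1))
      g2 <- randomDag(sample(3:8, 1), 0.35, sample.int(1e6, 1))
      s1 <- extractSubgraph(g1, sample(classIds(g1), 1), 2)
      s2 <- extractSubgraph(g2, sample(classIds(g2), 1), 2)
      got <- suppressMessages(blondelSimilarity(s1, s2))
      want <- blondelOracle(adjacencyMatrix(s1), adjacencyMatrix(s2))
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("pair %d", i))
      expect_gte(got, 0)
      expect_lte(got, 1)
      # swapping the arguments reads the transposed entry: same value
      expect_equal(suppressMessages(blondelSimilarity(s2, s1)), got,
                   tolerance = 1e-9)
    }
  })
  # identical chains: the generator pairing is the strongest in its row
  ch <- extractSubgraph(chainOntology(5), "a", 4)
  mA <- adjacencyMatrix(ch)
  Tm <- matrix(1, 5, 5)
  for (k in 1:100) {
    num <- mA %*% Tm %*% t(mA) + t(mA) %*% Tm %*% mA
    Tm <- num / sqrt(sum(num^2))
  }
  expect_equal(unname(which.max(Tm[1, ])), 1L)
})

test_that("the structure matrix covers exactly the name-unmatched classes", {
  pair <- deriveVariant(generateBaseOntology(40, seed = 13),
                        labelEditRate = 0.13, nSubtreeGrafts = 1, seed = 13)
  A <- ontologyA(pair)
  B <- ontologyB(pair)
  cfg <- fusionConfig()
  S <- buildNameMatrix(A, B, cfg)
  Tm <- buildStructureMatrix(A, B, S, cfg)
  unmatchedA <- rownames(S)[apply(S, 1, max) <= cfg@thetaN]
  expect_identical(rownames(Tm), unmatchedA)
  expect_true(all(Tm >= 0 & Tm <= 1))

  # all classes name-matched -> empty matrix
  Sfull <- buildNameMatrix(A, A, cfg)
  expect_message(T0 <- buildStructureMatrix(A, A, Sfull, cfg), "empty")
  expect_equal(dim(T0), c(0, 0))

  # one generator per side -> 1x1 matrix holding the pairwise metric
  a2 <- ontologyGraph(c("p", "q"), c("alpha", "strange one"),
                      edges = cbind("p", "q"))
  b2 <- ontologyGraph(c("r", "s"), c("alpha", "different name"),
                      edges = cbind("r", "s"))
  S2 <- buildNameMatrix(a2, b2, cfg)
  T2 <- buildStructureMatrix(a2, b2, S2, cfg)
  expect_equal(dim(T2), c(1, 1))
  expect_equal(T2["q", "s"],
               vectorialSimilarity(extractSubgraph(a2, "q", 4),
                                   extractSubgraph(b2, "s", 4), "cosine"))
})

test_that("every metric fills the matrix deterministically, threads included", {
  pair <- deriveVariant(generateBaseOntology(30, seed = 17),
                        labelEditRate = 0.15, seed = 17)
  A <- ontologyA(pair)
  B <- ontologyB(pair)
  for (m in c("cosine", "euclidean", "pearson", "constraint", "blondel")) {
    cfg <- fusionConfig(metric = m)
    S <- buildNameMatrix(A, B, cfg)
    T1 <- buildStructureMatrix(A, B, S, cfg)
    expect_true(all(T1 >= 0 & T1 <= 1), label = m)
    cfg2 <- fusionConfig(metric = m, threads = 2L)
    T2 <- buildStructureMatrix(A, B, S, cfg2)
    expect_identical(T1, T2, label = paste(m, "parallel"))
  }
})
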