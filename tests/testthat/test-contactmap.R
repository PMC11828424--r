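# ContactMap container, map arithmetic and fold partitioning.

randomSymMap <- function(n, clip = c(-2, 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- matrix(runif(n * n, -1, 1), n, n)
  V <- (V + t(V)) / 2
  ContactMap(V, binSize = 512L, clipRange = clip)
}

test_that("map signal strength equals the per-cell sum of squares", {
  expect_equal(mapSignalStrength(ContactMap(matrix(0, 4, 4))), 0)
  expect_equal(mapSignalStrength(ContactMap(matrix(c(1, -1, -1, 1), 2))), 4)

  set.seed(31)
  for (rep in 1:5) {
    m <- randomSymMap(10)
    brute <- 0
    V <- mapValues(m)
    for (a in 1:10) for (b in 1:10) brute <- brute + V[a, b]^2
    expect_equal(mapSignalStrength(m), brute, tolerance = 1e-12)
    # transpose invariance
    expect_equal(mapSignalStrength(ContactMap(t(V), binSize = 512L)),
                 mapSignalStrength(m))
  }
})

test_that("missing bins are excluded from sums and all-missing errors", {
  V <- matrix(1, 4, 4)
  m <- ContactMap(V, missingBins = c(TRUE, FALSE, FALSE, FALSE),
                  clipRange = c(-2, 2))
  expect_equal(mapSignalStrength(m), 9) # 3x3 usable cells
  allMiss <- ContactMap(V, missingBins = rep(TRUE, 4), clipRange = c(-2, 2))
  expect_error(mapSignalStrength(allMiss), "missing")
})

test_that("map difference score matches brute force and is a metric-like score", {
  expect_equal(mapDifferenceScore(randomSymMap(6, seed = 1),
                                  randomSymMap(6, seed = 1)), 0)
  V <- matrix(0, 8, 8)
  W <- V; W[3, 3] <- 2
  expect_equal(mapDifferenceScore(ContactMap(V), ContactMap(W)), 2)

  set.seed(7)
  for (rep in 1:5) {
    a <- randomSymMap(8); b <- randomSymMap(8)
    d2 <- 0
    for (i in 1:8) for (j in 1:8)
      d2 <- d2 + (mapValues(a)[i, j] - mapValues(b)[i, j])^2
    expect_equal(mapDifferenceScore(a, b), sqrt(d2), tolerance = 1e-12)
    expect_equal(mapDifferenceScore(a, b, method = "mse"), d2 / 64,
                 tolerance = 1e-12)
    expect_equal(mapDifferenceScore(a, b), mapDifferenceScore(b, a))
    cc <- randomSymMap(8)
    expect_lte(mapDifferenceScore(a, cc),
               mapDifferenceScore(a, b) + mapDifferenceScore(b, cc) + 1e-12)
  }
})

test_that("incompatible maps are rejected", {
  a <- randomSymMap(6, seed = 2); b <- randomSymMap(8, seed = 2)
  expect_error(mapDifferenceScore(a, b), "incompatible")
  c1 <- ContactMap(matrix(0, 6, 6), binSize = 512L,
                   missingBins = c(TRUE, rep(FALSE, 5)))
  expect_error(mapDifferenceScore(a, c1), "mask")
})

test_that("validity catches malformed maps", {
  expect_error(ContactMap(matrix(0, 3, 4)), "square")
  expect_error(ContactMap(matrix(5, 4, 4), clipRange = c(-2, 2)), "clip")
  V <- matrix(0, 4, 4); V[1, 2] <- 1 # asymmetric
  expect_error(ContactMap(V), "symmetric")
})

test_that("contact maps round-trip through the text container", {
  m <- randomSymMap(9, seed = 5)
  m@missingBins[c(2L, 7L)] <- TRUE
  path <- tempfile(fileext = ".tsv")
  writeContactMap(m, path)
  m2 <- readContactMap(path)
  expect_equal(mapValues(m2), mapValues(m), tolerance = 1e-14)
  expect_identical(missingBins(m2), missingBins(m))
  expect_identical(binSize(m2), binSize(m))
  expect_equal(clipRange(m2), clipRange(m))
})

test_that("fold partitioning keeps aligned components together", {
  regs <- data.frame(id = LETTERS[1:8], chrom = "chr1",
                     start = 0, end = 5e6)
  # no pairs, 8 folds: perfectly balanced singletons
  f <- partitionFolds(regs, NULL, nFolds = 8)
  expect_setequal(unname(f), 1:8)

  f2 <- partitionFolds(regs, data.frame(a = c("A", "B"), b = c("B", "C")),
                       nFolds = 8)
  expect_true(f2["A"] == f2["B"] && f2["B"] == f2["C"])

  allPairs <- t(combn(LETTERS[1:8], 2))
  f3 <- partitionFolds(regs, as.data.frame(allPairs), nFolds = 4)
  expect_length(unique(unname(f3)), 1L)

  expect_error(partitionFolds(regs, data.frame(a = "A", b = "Z")), "unknown")
})

test_that("fold partitioning never splits components and balances sizes", {
  # independent union-find oracle
  uf <- function(ids, pairs) {
    parent <- stats::setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    if (nrow(pairs)) for (r in seq_len(nrow(pairs)))
      parent[[find(pairs[r, 1])]] <- find(pairs[r, 2])
    vapply(ids, find, character(1L))
  }
  set.seed(17)
  for (rep in 1:10) {
    nR <- sample(10:24, 1)
    ids <- paste0("r", seq_len(nR))
    regs <- data.frame(id = ids, chrom = "chr1", start = 0,
                       end = sample(c(1e6, 2e6, 5e6), nR, TRUE))
    nP <- sample(0:10, 1)
    pairs <- if (nP) data.frame(a = sample(ids, nP, TRUE),
                                b = sample(ids, nP, TRUE)) else NULL
    f <- partitionFolds(regs, pairs, nFolds = 4)
    roots <- uf(ids, if (is.null(pairs)) matrix(nrow = 0, ncol = 2)
                else as.matrix(pairs))
    for (r in unique(roots))
      expect_length(unique(unname(f[names(roots)[roots == r]])), 1L)
  }
  # equal-size components, c * nFolds of them: near-perfect balance
  regs <- data.frame(id = paste0("r", 1:12), chrom = "chr1",
                     start = 0, end = 1e6)
  f <- partitionFolds(regs, NULL, nFolds = 4)
  bp <- table(f) # 3 regions per fold
  expect_lte(max(bp) / min(bp), 1 + 1 / 3)
})

test_that("score panels reduce by sequential averaging", {
  a <- array(1:8, dim = c(1, 2, 2, 2),
             dimnames = list(subject = "s", permutation = c("p1", "p2"),
                             target = c("t1", "t2"), model = c("m1", "m2")))
  p <- ScorePanel(a)
  expect_equal(unname(reduceScores(p)), mean(1:8))
  one <- array(3.14, dim = c(1, 1, 1, 1),
               dimnames = list(subject = "s", permutation = "p",
                               target = "t", model = "m"))
  expect_equal(unname(reduceScores(ScorePanel(one))), 3.14)
  expect_error(ScorePanel(array(1, dim = c(2, 2))), "named dimnames")
})
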