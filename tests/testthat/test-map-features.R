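# Insulation, dot scoring, boundary calling, Li threshold, sensitivity
# classification and orientation histograms.

test_that("insulation profile equals the brute-force diamond mean", {
  cm <- ContactMap(matrix(0.5, 20, 20), clipRange = c(-2, 2))
  prof <- profileValues(insulationProfile(cm, 4L))
  expect_true(all(is.na(prof[c(1:4, 18:20)])))
  expect_equal(unique(prof[5:17]), 0.5)

  set.seed(3)
  V <- matrix(runif(400, -1, 1), 20, 20); V <- (V + t(V)) / 2
  m <- ContactMap(V, clipRange = c(-2, 2))
  for (w in c(2L, 5L)) {
    expect_equal(profileValues(insulationProfile(m, w)), bruteInsulation(V, w),
                 tolerance = 1e-12)
  }
  # missing-bin path agrees with the dense path where defined
  m2 <- ContactMap(V, missingBins = c(rep(FALSE, 19), TRUE), clipRange = c(-2, 2))
  p2 <- profileValues(insulationProfile(m2, 2L))
  pd <- profileValues(insulationProfile(m, 2L))
  expect_equal(p2[3:16], pd[3:16], tolerance = 1e-12)

  expect_error(insulationProfile(cm, 10L), "invalid window")
  # transposition invariance for symmetric maps
  expect_equal(profileValues(insulationProfile(ContactMap(t(V), clipRange = c(-2, 2)), 3L)),
               profileValues(insulationProfile(m, 3L)))
})

test_that("insulation offset recovers planted boundary displacement", {
  n <- 96L
  center <- n %/% 2L + 1L
  m0 <- synthMap(n, boundaries = data.frame(bin = center, depth = 1))
  expect_equal(insulationOffset(m0, 8L), 0)

  m8 <- synthMap(n, boundaries = data.frame(bin = center + 8L, depth = 1))
  expect_equal(insulationOffset(m8, 8L), 8 * 2048)

  flat <- synthMap(n)
  expect_true(is.na(insulationOffset(flat, 8L)))
})

test_that("asymmetric cassettes shift the insulation minimum, growing with window size", {
  params <- surrogateParams(shadeFrac = 0.6, shadeDecay = 0.97)
  pred <- fgPred(nBins = 128L, binSize = 2048L, params = params)
  bg <- fgCleanBg(pred, seed = 3L)
  site <- fgStrongSite()
  offFor <- function(ori) {
    s <- assembleInsertion(bg, insertionLayout(site, orientations = ori,
                                               spacingBp = 180L))
    m <- predictContacts(pred, s)[[1L]]
    vapply(c(4L, 16L, 32L), function(w) insulationOffset(m, w), numeric(1L))
  }
  sym <- abs(offFor("<<<>>>"))
  asym <- abs(offFor(">>>>>>"))
  expect_true(all(asym >= sym))
  expect_true(all(diff(asym) >= 0))
  expect_gt(asym[3L], asym[1L]) # grows with window size
  # direction tracks cassette polarity
  s <- assembleInsertion(bg, insertionLayout(site, orientations = "<<<<<<",
                                             spacingBp = 180L))
  expect_lt(insulationOffset(predictContacts(pred, s)[[1L]], 32L), 0)
})

test_that("dot score has the documented closed forms", {
  z <- ContactMap(matrix(0, 20, 20))
  expect_equal(dotScore(z, 10, 10), 0)
  u <- ContactMap(matrix(0.7, 20, 20), clipRange = c(-2, 2))
  expect_equal(dotScore(u, 10, 10), 0)

  V <- matrix(0, 20, 20)
  V[9:11, 9:11] <- 1
  m <- ContactMap(V, clipRange = c(-2, 2))
  expect_equal(dotScore(m, 10, 10), 1)
  # patch transposition invariance
  expect_equal(dotScore(ContactMap(t(V), clipRange = c(-2, 2)), 10, 10),
               dotScore(m, 10, 10))
  expect_error(dotScore(z, 3, 10), "invalid anchor")
})

test_that("boundary calling respects prominence with leftmost plateau ties", {
  expect_identical(nrow(callBoundaries(1:20 / 10, prominence = 0.01)), 0L)

  v <- rep(0, 40)
  v[10] <- -1      # deep dip
  v[30] <- -0.2    # shallow dip
  calls <- callBoundaries(v, prominence = 0.5)
  expect_identical(calls$bin, 10L)
  callsAll <- callBoundaries(v, prominence = 0.1)
  expect_setequal(callsAll$bin, c(10L, 30L))

  # plateau minimum reported at its leftmost bin
  vp <- rep(0, 20); vp[8:11] <- -1
  expect_identical(callBoundaries(vp, prominence = 0.5)$bin, 8L)

  # brute-force prominence oracle on random profiles
  set.seed(23)
  bruteProm <- function(y) { # prominences of strict minima of y
    out <- list()
    n <- length(y)
    for (p in 2:(n - 1)) {
      if (!(y[p] < y[p - 1] && y[p] <= y[p + 1])) next
      if (y[p] == y[p + 1]) next # plateau handled separately
      h <- -y[p]
      yy <- -y
      lhs <- which(yy[1:(p - 1)] > h)
      lb <- if (length(lhs)) min(yy[(max(lhs) + 1):(p - 1)]) else min(yy[1:(p - 1)])
      rhs <- which(yy[(p + 1):n] > h)
      rb <- if (length(rhs)) min(yy[(p + 1):(p + min(rhs) - 1)]) else min(yy[(p + 1):n])
      out[[length(out) + 1L]] <- c(p, h - max(lb, rb))
    }
    do.call(rbind, out)
  }
  for (rep in 1:5) {
    y <- round(cumsum(rnorm(60)), 2)
    got <- callBoundaries(y, prominence = 0)
    oracle <- bruteProm(y)
    if (is.null(oracle)) next
    keyGot <- got[got$bin %in% oracle[, 1], ]
    expect_equal(keyGot$prominence,
                 oracle[match(keyGot$bin, oracle[, 1]), 2], tolerance = 1e-9)
  }
})

test_that("Li threshold separates modes, matches an independent minimiser, scales", {
  set.seed(13)
  x <- c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1))
  t1 <- liThreshold(x)
  expect_gt(t1, 1); expect_lt(t1, 9)

  # independent oracle: brute-force minimum cross-entropy split
  bruteLi <- function(v) {
    v <- sort(v); shift <- min(v) - 1e-6 * diff(range(v)); y <- v - shift
    cands <- (y[-1] + y[-length(y)]) / 2
    ce <- vapply(cands, function(t) {
      m0 <- mean(y[y <= t]); m1 <- mean(y[y > t])
      -(sum(y[y <= t]) * log(m0) + sum(y[y > t]) * log(m1))
    }, numeric(1L))
    cands[which.min(ce)] + shift
  }
  for (v in list(c(1, 2), c(1, 1.5, 8, 9), x)) {
    tPkg <- liThreshold(v)
    tOr <- bruteLi(v)
    # same induced split
    expect_identical(v <= tPkg, v <= tOr)
  }

  expect_equal(liThreshold(3 * x), 3 * t1, tolerance = 1e-6)
  expect_error(liThreshold(rep(2, 10)), "degenerate")
})

test_that("sensitivity classification is thresholded, localised and monotone", {
  tiles <- data.frame(offset = seq(-45056L, 43008L, by = 2048L),
                      score = 0)
  r <- classifySensitivity(tiles, threshold = 1)
  expect_false(r$sensitive)

  tiles2 <- tiles
  tiles2$score[tiles2$offset == 4096L] <- 5
  r2 <- classifySensitivity(tiles2, threshold = 1)
  expect_true(r2$sensitive)
  expect_identical(r2$argmaxOffset, 4096L)

  # a high tile outside the +/-28 kb window does not count
  tiles3 <- tiles
  tiles3$score[tiles3$offset == -45056L] <- 99
  expect_false(classifySensitivity(tiles3, threshold = 1)$sensitive)

  # no tiles in window: unscored
  far <- data.frame(offset = c(-90000L, 90000L), score = c(9, 9))
  expect_true(is.na(classifySensitivity(far, threshold = 1)$sensitive))

  # monotone: raising any tile never flips sensitive -> resilient
  set.seed(91)
  for (rep in 1:20) {
    sc <- runif(44, 0, 2)
    t4 <- tiles; t4$score <- sc
    before <- classifySensitivity(t4, threshold = 1)$sensitive
    t5 <- t4; k <- sample(44, 1); t5$score[k] <- t5$score[k] + runif(1, 0, 3)
    after <- classifySensitivity(t5, threshold = 1)$sensitive
    expect_true(!before || after)
  }
})

test_that("orientation histogram applies the all-co-oriented rule", {
  sites <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(1000, 1100, 5000, 5100, 9000), width = 19),
    strand = c("+", "+", "+", "-", "-"))
  calls <- data.frame(chrom = "chr1",
                      boundary = c(500, 4800, 8900, 20000),
                      argmaxOffset = c(448, 100, 0, -2048))
  oh <- orientationHistogram(calls, sites)
  expect_identical(oh$calls$orientation, c("right", "other", "left", "other"))

  strandless <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, width = 19))
  expect_error(orientationHistogram(calls, strandless), "strand")
})

test_that("planted orientation asymmetry is reproduced in the histogram", {
  # left-oriented sites upstream of boundaries, right-oriented downstream
  set.seed(7)
  nb <- 30L
  boundaries <- seq(50000L, by = 60000L, length.out = nb)
  off <- ifelse(seq_len(nb) %% 2 == 0, -4096L, 4096L)
  siteStrand <- ifelse(off < 0, "-", "+")
  sites <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = boundaries + off + 1000L, width = 19),
    strand = siteStrand)
  calls <- data.frame(chrom = "chr1", boundary = boundaries, argmaxOffset = off)
  oh <- orientationHistogram(calls, sites)
  h <- oh$histogram
  expect_gt(h$left[h$offset_tiles == -2], 0)
  expect_identical(h$right[h$offset_tiles == -2], 0)
  expect_gt(h$right[h$offset_tiles == 2], 0)
  expect_identical(h$left[h$offset_tiles == 2], 0)
  expect_identical(nrow(oh$smoothed), nrow(h))
})
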