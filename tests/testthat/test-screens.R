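# Assembly and the virtual-insertion experiment designs.

test_that("assembly replaces residues in place with correct geometry", {
  bg <- strrep("A", 4096L)
  cons <- fgConsensus()
  out <- assembleInsertion(bg, insertionLayout(ctcfSite(cons)))
  expect_identical(nchar(out), 4096L)
  diffs <- which(strsplit(out, "")[[1L]] != "A")
  expect_identical(length(diffs), sum(strsplit(cons, "")[[1L]] != "A"))
  expect_lte(diff(range(diffs)), 18L) # all changes within one 19-bp slot
  st <- (4096L - 19L) %/% 2L + 1L
  expect_identical(substr(out, st, st + 18L), cons)

  # ten sites at 180-bp gaps: cassette spans 10*19 + 9*180 = 1810 bp
  out10 <- assembleInsertion(bg, insertionLayout(ctcfSite(cons), n = 10L,
                                                 spacingBp = 180L))
  diffs10 <- which(strsplit(out10, "")[[1L]] != "A")
  expect_lte(diff(range(diffs10)) + 1L, 1810L)
  expect_gte(diff(range(diffs10)) + 1L, 1810L - 40L) # ends may match background

  # '<' element writes the reverse complement of the full unit
  site <- ctcfSite(cons, "GGG", "CC")
  outR <- assembleInsertion(bg, insertionLayout(site, orientations = "<"))
  expect_true(grepl(revComp(siteSequence(site)), outR, fixed = TRUE))
})

test_that("assembly rejects invalid layouts", {
  bg <- strrep("A", 1000L)
  site <- fgStrongSite()
  expect_error(assembleInsertion(bg, insertionLayout(site, n = 3L, spacingBp = 10L)),
               "overlap")
  expect_error(assembleInsertion(bg, insertionLayout(site, anchor = 600)),
               "window")
  expect_identical(assembleInsertion(bg, emptyLayout()), bg)
})

test_that("a layout and its mirror are reverse-complement-equal on a palindromic background", {
  set.seed(57)
  half <- paste(sample(c("A", "C", "G", "T"), 2048, TRUE), collapse = "")
  bg <- paste0(half, revComp(half)) # revComp(bg) == bg
  expect_identical(revComp(bg), bg)
  site <- fgStrongSite(10L)
  # two-site cassette (even span, so the mirrored cassette lands in place)
  fwd <- assembleInsertion(bg, insertionLayout(site, orientations = ">>",
                                               spacingBp = 100L))
  mir <- assembleInsertion(bg, insertionLayout(site, orientations = "<<",
                                               spacingBp = 100L))
  expect_identical(revComp(fwd), mir)
})

test_that("flank sweep rises with GC flank length and saturates at the flank window", {
  pred <- fgPred()
  bgA <- strrep("A", windowSize(pred))
  site <- ctcfSite(fgConsensus(), strrep("G", 35), strrep("C", 35))
  fs <- flankSweep(site, pred, bgA, lengths = c(0, 5, 10, 15, 25, 35))
  expect_true(all(diff(fs$score) >= -1e-9))
  expect_gt(fs$score[fs$flank_bp == 15], fs$score[fs$flank_bp == 0])
  # flat beyond the surrogate's 15-bp flank window
  expect_equal(fs$score[fs$flank_bp == 35], fs$score[fs$flank_bp == 15],
               tolerance = 1e-9)
  # length-0 point equals the flankless site scored directly
  bare <- reduceScores(insertionScore(bgA, insertionLayout(ctcfSite(fgConsensus())), pred))
  expect_equal(fs$score[fs$flank_bp == 0], unname(bare), tolerance = 1e-12)

  expect_error(ctcfSite(strrep("N", 19)), "A,C,G,T")
  expect_error(flankSweep(fgStrongSite(10L), pred, bgA, lengths = 0:20),
               "insufficient")
})

test_that("multiplicative core and flank factors give an exactly rank-1 screen", {
  pred <- fgPred()
  bgA <- strrep("A", windowSize(pred))
  set.seed(9)
  cores <- lapply(c(0, 1, 1, 2), function(k)
    ctcfSite(if (k == 0) fgConsensus() else mutateCore(fgConsensus(), k),
             id = paste0("c", k, sample(100, 1))))
  flanks <- lapply(c(1, 0.8, 0.6, 0.4), function(gc)
    fgRandomFlanks(gc, id = paste0("f", gc)))
  cf <- coreFlankScreen(cores, flanks, pred, bgA)
  expect_lt(cf@residual / sqrt(sum(cf@M^2)), 1e-10)
  expect_identical(length(cfCognate(cf)), 4L)
  expect_error(coreFlankScreen(cores[1:2], flanks, pred, bgA), "length")
})

test_that("SVD factors recover planted strengths and closed forms", {
  # constant matrix: constant singular vectors, d[1] = n * value
  n <- 6L
  cf <- coreFlankMatrix(matrix(2, n, n))
  expect_equal(cf@d[1L], n * 2)
  expect_equal(max(abs(cf@u - cf@u[1L])), 0, tolerance = 1e-12)
  expect_equal(max(abs(cf@v - cf@v[1L])), 0, tolerance = 1e-12)

  # planted multiplicative structure, exact at zero noise
  set.seed(41)
  cStr <- runif(50, 0.2, 1); fStr <- runif(50, 0.2, 1)
  M0 <- cStr %o% fStr
  cf0 <- coreFlankMatrix(M0)
  expect_lt(cf0@residual, 1e-10)
  expect_gt(cor(cfCoreStrengths(cf0), cStr), 1 - 1e-12)

  M <- M0 + matrix(rnorm(2500, sd = 0.05 * max(M0)), 50, 50)
  cfN <- coreFlankMatrix(M)
  expect_gte(cor(cfCoreStrengths(cfN), cStr), 0.99)
  expect_gte(cor(cfFlankStrengths(cfN), fStr), 0.99)
  # rank-k residual is non-increasing in k
  sv <- svd(M)
  resid <- vapply(1:5, function(k) {
    approx <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    sqrt(sum((M - approx)^2))
  }, numeric(1L))
  expect_true(all(diff(resid) <= 1e-9))
})

test_that("saturation mutagenesis zeroes the reference and penalises consensus loss", {
  pred <- fgPred()
  bgA <- strrep("A", windowSize(pred))
  site <- ctcfSite(fgConsensus(), strrep("G", 15), strrep("C", 15))
  sm <- saturationMutagenesis(site, pred, bgA, positions = c(16L, 20L, 25L))
  region <- attr(sm, "region")
  for (p in c(16L, 20L, 25L))
    expect_equal(unname(sm[p, substr(region, p, p)]), 0)
  # high-information core position: consensus -> worst base is deleterious
  expect_lt(min(sm[25L, ], na.rm = TRUE), 0)

  # end-to-end recomputation of one entry
  mutReg <- region; substr(mutReg, 20L, 20L) <- "T"
  mutSite <- ctcfSite(substr(mutReg, 16, 34), substr(mutReg, 1, 15),
                      substr(mutReg, 35, 49))
  d <- reduceScores(insertionScore(bgA, insertionLayout(mutSite), pred)) -
    reduceScores(insertionScore(bgA, insertionLayout(site), pred))
  expect_equal(unname(sm[20L, "T"]), unname(d), tolerance = 1e-10)
})

test_that("pairwise mutagenesis is additive for a linear surrogate and symmetric", {
  params <- surrogateParams(strengthTransform = "linear", gamma = 0,
                            threshold = -4)
  pred <- fgPred(params = params)
  bgA <- strrep("A", windowSize(pred))
  site <- ctcfSite(fgConsensus(), strrep("G", 15), strrep("C", 15))
  pos <- c(18L, 20L, 24L, 25L, 29L)
  mt <- pairwiseMutagenesis(list(site), pred, bgA, positions = pos)
  obs <- mt@pairwise; add <- mt@additive
  expect_equal(obs, t(obs))
  ok <- !is.na(obs)
  expect_lt(max(abs(obs[ok] - add[ok])), 1e-8)
  expect_error(pairwiseMutagenesis(list(), pred, bgA), "empty")
})

test_that("grammar screens: dosage, tandem symmetry and convergent dots", {
  pred <- fgPred()
  bg <- fgCleanBg(pred)
  site <- fgStrongSite()
  g <- grammarScreen(site, pred, bg, nSites = 1:3, spacings = 180L)
  expect_true(all(diff(g$score) > 0))

  g2 <- grammarScreen(site, pred, bg, orientations = c(">>", "<<"),
                      spacings = 2000L)
  expect_equal(g2$score[1L], g2$score[2L], tolerance = 1e-9)

  # convergent orientation places a dot at the anchors, divergent does not
  predW <- fgPred(nBins = 64L, binSize = 2048L)
  bgW <- fgCleanBg(predW, seed = 7L)
  n <- windowSize(predW)
  span <- 38L + 60000L
  first <- (n - span) %/% 2L + 1L
  anchors <- c(((first + 9L - 1L) %/% 2048L) + 1L,
               ((first + 19L + 60000L + 9L - 1L) %/% 2048L) + 1L)
  dsc <- vapply(c("><", "<>"), function(ori) {
    s <- assembleInsertion(bgW, insertionLayout(site, orientations = ori,
                                                spacingBp = 60000L))
    dotScore(predictContacts(predW, s)[[1L]], anchors[1L], anchors[2L])
  }, numeric(1L))
  expect_gt(dsc["><"], dsc["<>"])
  expect_gt(dsc["><"], 0)
})

test_that("dot and boundary scenarios rank sites consistently", {
  predW <- fgPred(nBins = 64L, binSize = 2048L)
  bgW <- fgCleanBg(predW, seed = 7L)
  strong <- fgStrongSite()
  weakCore <- ctcfSite(mutateCore(fgConsensus(), 2, seed = 8),
                       strrep("G", 30), strrep("C", 30), id = "weak")
  sStrong <- dotBoundaryScenarios(strong, predW, bgW, dotSpacing = 60000L)
  sWeak <- dotBoundaryScenarios(weakCore, predW, bgW, dotSpacing = 60000L)
  expect_gt(sStrong$boundary, sWeak$boundary)
  expect_gt(sStrong$dot, sWeak$dot)
  expect_gt(sStrong$boundary, 0)
  expect_gt(sStrong$dot, 0)

  # determinism: identical sites give identical score pairs
  again <- dotBoundaryScenarios(fgStrongSite(), predW, bgW, dotSpacing = 60000L)
  expect_identical(again$boundary, sStrong$boundary)
  expect_identical(again$dot, sStrong$dot)

  # zero-strength site: nothing above threshold, nothing to score
  dead <- ctcfSite(strrep("A", 19), strrep("G", 30), strrep("C", 30))
  sDead <- dotBoundaryScenarios(dead, predW, bgW, dotSpacing = 60000L)
  expect_lt(abs(sDead$boundary), 1e-9)
  expect_lt(abs(sDead$dot), 1e-9)

  expect_error(dotBoundaryScenarios(strong, predW, bgW, dotSpacing = 400000L),
               "window too small")
})

test_that("scores are invariant under reverse complement of the whole window", {
  pred <- fgPred()
  bg <- fgCleanBg(pred)
  site <- fgStrongSite()
  lay <- insertionLayout(site, orientations = "><", spacingBp = 4000L)
  mirror <- insertionLayout(site, orientations = "><", spacingBp = 4000L)
  fwd <- reduceScores(insertionScore(bg, lay, pred))
  # assembling on the reverse-complemented background and flipping back
  s1 <- assembleInsertion(bg, lay)
  rcScore <- mapDifferenceScore(predictContacts(pred, revComp(bg))[[1L]],
                                predictContacts(pred, revComp(s1))[[1L]])
  expect_equal(unname(fwd), rcScore, tolerance = 1e-9)
})
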