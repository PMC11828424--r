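# Map-level statistics: insulation, dots, boundary calling and
# sensitivity classification.

#' InsulationProfile: sliding-diamond insulation along the diagonal
#'
#' @slot values Per-bin insulation values (NA where the full diamond does
#'   not fit).
#' @slot windowBins Diamond half-width in bins.
#' @slot binSize Bin size in bp.
#' @name InsulationProfile-class
#' @aliases InsulationProfile
#' @export
setClass("InsulationProfile",
  slots = c(values = "numeric", windowBins = "integer", binSize = "integer"))

#' @rdname InsulationProfile-class
#' @param x An `InsulationProfile`.
#' @export
profileValues <- function(x) x@values

setMethod("show", "InsulationProfile", function(object) {
  cat("InsulationProfile:", length(object@values), "bins, window",
      object@windowBins, "bins (", object@windowBins * object@binSize / 1000,
      "kb )\n")
})

#' Insulation profile of a contact map
#'
#' The value at bin `i` is the mean of the off-diagonal `w x w` square of
#' cells connecting the `w` bins left of `i` (exclusive) with the `w` bins
#' from `i` rightwards: rows `i-w ... i-1`, columns `i ... i+w-1` (1-based).
#' Bins where the full square does not fit are undefined (NA). Window sizes
#' of 16, 64 and 128 bins at 2048-bp resolution correspond to 32.8 kb,
#' 131 kb and 262.1 kb diamonds.
#'
#' @param map A [ContactMap-class].
#' @param windowBins Diamond half-width `w` in bins (`2*w < nBins`).
#' @return An [InsulationProfile-class].
#' @export
insulationProfile <- function(map, windowBins) {
  stopifnot(is(map, "ContactMap"))
  w <- .checkScalarInt(windowBins, "windowBins")
  n <- nBins(map)
  if (2L * w >= n) stop("invalid window: 2*windowBins must be < nBins")
  V <- mapValues(map)
  vals <- rep(NA_real_, n)
  if (any(missingBins(map))) {
    V[missingBins(map), ] <- NA
    V[, missingBins(map)] <- NA
    for (i in (w + 1L):(n - w + 1L))
      vals[i] <- mean(V[(i - w):(i - 1L), i:(i + w - 1L)], na.rm = TRUE)
  } else {
    # summed-area table: diamond sums in O(1) per bin
    P <- matrix(0, n + 1L, n + 1L)
    P[-1L, -1L] <- t(apply(apply(V, 2L, cumsum), 1L, cumsum))
    for (i in (w + 1L):(n - w + 1L)) {
      a1 <- i - w; a2 <- i - 1L; b1 <- i; b2 <- i + w - 1L
      vals[i] <- (P[a2 + 1L, b2 + 1L] - P[a1, b2 + 1L] -
                    P[a2 + 1L, b1] + P[a1, b1]) / (w * w)
    }
  }
  new("InsulationProfile", values = vals, windowBins = w,
      binSize = binSize(map))
}

#' Insulation offset: distance of the insulation minimum from the center
#'
#' Finds the minimum of the insulation profile and reports its signed
#' distance in bp from the map center bin (`floor(n/2) + 1`). Ties are
#' broken toward the center, then leftward. A flat profile has no minimum
#' and yields NA.
#'
#' @param map A [ContactMap-class] or [InsulationProfile-class].
#' @param windowBins Diamond half-width (when `map` is a ContactMap).
#' @return Signed offset in bp, or NA when the profile is flat.
#' @export
insulationOffset <- function(map, windowBins = NULL) {
  prof <- if (is(map, "InsulationProfile")) map else
    insulationProfile(map, windowBins)
  v <- prof@values
  n <- length(v)
  ok <- which(!is.na(v))
  if (!length(ok)) stop("profile has no defined values")
  if (diff(range(v[ok])) < 1e-12) return(NA_real_)
  center <- n %/% 2L + 1L
  mn <- min(v[ok])
  cand <- ok[v[ok] <= mn + 1e-12]
  best <- cand[order(abs(cand - center), cand)][1L]
  (best - center) * as.numeric(prof@binSize)
}

#' Dot score at an anchor pixel
#'
#' Applies a 13 x 13 bin kernel centered at `(i, j)`: a 3 x 3 center over
#' the anticipated dot, flanked inside the footprint by four 3-bin-wide
#' arms (the up/down arms are 5 x 3, left/right 3 x 5; opposing arm pairs
#' total 10 x 3). The score is RMS(center) - RMS(arms) where RMS is the
#' square root of the mean of squared values, so any uniform patch scores
#' exactly 0.
#'
#' @param map A [ContactMap-class].
#' @param i,j Anchor bin (1-based); the full footprint must fit.
#' @return Numeric scalar.
#' @export
dotScore <- function(map, i, j) {
  stopifnot(is(map, "ContactMap"))
  n <- nBins(map)
  if (i - 6L < 1L || i + 6L > n || j - 6L < 1L || j + 6L > n)
    stop("invalid anchor: 13x13 patch does not fit in the map")
  V <- mapValues(map)
  patch <- V[(i - 6L):(i + 6L), (j - 6L):(j + 6L)]
  center <- patch[6:8, 6:8]
  arms <- c(patch[1:5, 6:8], patch[9:13, 6:8], patch[6:8, 1:5], patch[6:8, 9:13])
  rms <- function(x) sqrt(mean(x^2))
  rms(center) - rms(arms)
}

#' Call boundaries from an insulation profile
#'
#' Boundaries are local minima of the insulation profile with prominence at
#' or above a threshold. Prominence of a minimum is its depth relative to
#' the lower of the two saddle levels that separate it from deeper minima
#' (profile ends count as open sides). A plateau minimum is reported at its
#' leftmost bin.
#'
#' @param profile An [InsulationProfile-class] (or numeric vector).
#' @param prominence Minimum prominence in map units (default 0.1).
#' @return data.frame with columns `bin`, `value`, `prominence` (possibly
#'   zero rows).
#' @export
callBoundaries <- function(profile, prominence = 0.1) {
  v <- if (is(profile, "InsulationProfile")) profile@values else as.numeric(profile)
  idx <- which(!is.na(v))
  if (!length(idx)) return(data.frame(bin = integer(), value = numeric(),
                                      prominence = numeric()))
  y <- -v[idx] # peaks of y are minima of v
  m <- length(y)
  peaks <- integer(0)
  iPos <- 1L
  while (iPos <= m) {
    j <- iPos
    while (j < m && y[j + 1L] == y[iPos]) j <- j + 1L
    leftUp <- iPos == 1L || y[iPos - 1L] < y[iPos]
    rightUp <- j == m || y[j + 1L] < y[iPos]
    interior <- iPos > 1L && j < m
    if (leftUp && rightUp && interior) peaks <- c(peaks, iPos)
    iPos <- j + 1L
  }
  if (!length(peaks)) return(data.frame(bin = integer(), value = numeric(),
                                        prominence = numeric()))
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    # walk left to the first strictly higher point; base is the min between
    lhs <- which(y[seq_len(p - 1L)] > h)
    leftBase <- if (length(lhs)) min(y[(max(lhs) + 1L):(p - 1L)]) else min(y[seq_len(p - 1L)])
    rhs <- which(y[(p + 1L):m] > h)
    rightBase <- if (length(rhs)) min(y[(p + 1L):(p + min(rhs) - 1L)]) else min(y[(p + 1L):m])
    h - max(leftBase, rightBase)
  }, numeric(1L))
  keep <- prom >= prominence
  data.frame(bin = idx[peaks[keep]], value = v[idx[peaks[keep]]],
             prominence = prom[keep])
}

#' Li's minimum cross-entropy threshold
#'
#' Iterative minimum cross-entropy thresholding on a sample of scores,
#' used to split boundary disruption scores into sensitive (high) versus
#' resilient (low) classes. The scores are shifted to a strictly positive
#' scale (shift proportional to the data range, so the threshold is scale-
#' and shift-equivariant), then the classic fixed-point iteration
#' `t <- (mu1 - mu0) / (log(mu1) - log(mu0))` is run to convergence.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @param tol Convergence tolerance relative to the data range.
#' @param maxIter Iteration cap.
#' @return Numeric threshold strictly inside the data range.
#' @export
liThreshold <- function(scores, tol = 1e-10, maxIter = 500L) {
  x <- scores[is.finite(scores)]
  if (length(unique(x)) < 2L)
    stop("degenerate distribution: need at least two distinct values")
  rng <- diff(range(x))
  shift <- min(x) - 1e-6 * rng
  y <- x - shift
  t <- mean(y)
  for (k in seq_len(maxIter)) {
    lowMean <- mean(y[y <= t])
    highMean <- mean(y[y > t])
    if (!is.finite(highMean) || !is.finite(lowMean)) break
    tNew <- (highMean - lowMean) / (log(highMean) - log(lowMean))
    if (abs(tNew - t) < tol * rng) { t <- tNew; break }
    t <- tNew
  }
  t + shift
}

#' Classify boundary sensitivity from tiled disruption scores
#'
#' A boundary is disruption-sensitive when the maximum tiled disruption
#' score within a window of the boundary (default +/-28 kb, i.e. 14 tiles
#' of 2048 bp per side) reaches a threshold, typically from [liThreshold].
#' Records the offset of the highest-scoring tile. With no tiles in the
#' window the boundary is unscored.
#'
#' @param tiles data.frame from [tiledDisruption] (`offset`, `score`).
#' @param threshold Sensitivity threshold.
#' @param windowBp Half-window in bp around the boundary (default 28,672).
#' @param tileBp Tile width in bp.
#' @return List with `sensitive` (TRUE/FALSE/NA for unscored), `maxScore`,
#'   `argmaxOffset` (bp, tile left edge).
#' @export
classifySensitivity <- function(tiles, threshold, windowBp = 28672L,
                                tileBp = 2048L) {
  centers <- tiles$offset + tileBp / 2
  inWin <- abs(centers) <= windowBp
  if (!any(inWin))
    return(list(sensitive = NA, maxScore = NA_real_,
                argmaxOffset = NA_integer_))
  sub <- tiles[inWin, , drop = FALSE]
  k <- which.max(sub$score)
  list(sensitive = sub$score[k] >= threshold, maxScore = sub$score[k],
       argmaxOffset = sub$offset[k])
}

#' Orientation histogram of sensitive boundary bins
#'
#' For each boundary, the highest-scoring disruption tile is overlapped
#' with stranded motif sites: a tile whose sites are all on `+` is
#' right-oriented, all on `-` left-oriented, mixed or empty tiles are
#' "other". Counts are histogrammed over the signed tile offset from the
#' boundary, and the total count profile is smoothed by a cubic smoothing
#' spline followed by a Gaussian kernel.
#'
#' @param calls data.frame with columns `chrom`, `boundary` (bp position)
#'   and `argmaxOffset` (bp, from [classifySensitivity]).
#' @param sites A [GenomicRanges::GRanges] of motif sites with strand
#'   (`+`/`-`; strandless sites are an error).
#' @param tileBp Tile width in bp.
#' @param smoothSigmaTiles Gaussian kernel width, in tiles.
#' @return List with `calls` (input plus `orientation`), `histogram`
#'   (data.frame offset_tiles x left/right/other counts) and `smoothed`
#'   (data.frame offset_tiles, total).
#' @importFrom GenomicRanges GRanges findOverlaps strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @export
orientationHistogram <- function(calls, sites, tileBp = 2048L,
                                 smoothSigmaTiles = 1) {
  st <- as.character(GenomicRanges::strand(sites))
  if (any(st == "*")) stop("sites must carry strand information")
  tileGr <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(start = calls$boundary + calls$argmaxOffset,
                     width = tileBp))
  ov <- GenomicRanges::findOverlaps(tileGr, sites)
  orientation <- rep("other", nrow(calls))
  for (q in unique(S4Vectors::queryHits(ov))) {
    ss <- st[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == q]]
    if (all(ss == "+")) orientation[q] <- "right"
    else if (all(ss == "-")) orientation[q] <- "left"
  }
  calls$orientation <- orientation

  offT <- calls$argmaxOffset / tileBp
  grid <- seq(min(offT), max(offT), by = 1)
  hist <- data.frame(offset_tiles = grid)
  for (cls in c("left", "right", "other"))
    hist[[cls]] <- vapply(grid, function(g)
      sum(offT == g & orientation == cls), numeric(1L))
  total <- rowSums(hist[, c("left", "right", "other")])

  smoothedTotal <- total
  if (length(grid) >= 4L && stats::sd(total) > 0) {
    sp <- stats::smooth.spline(grid, total)
    smoothedTotal <- stats::predict(sp, grid)$y
  }
  if (smoothSigmaTiles > 0) {
    w <- stats::dnorm(seq(-ceiling(3 * smoothSigmaTiles), ceiling(3 * smoothSigmaTiles)),
                      sd = smoothSigmaTiles)
    pad <- (length(w) - 1L) / 2L
    ext <- c(rep(smoothedTotal[1L], pad), smoothedTotal,
             rep(smoothedTotal[length(smoothedTotal)], pad))
    smoothedTotal <- vapply(seq_along(smoothedTotal), function(k)
      sum(ext[k:(k + 2L * pad)] * w) / sum(w), numeric(1L))
  }
  list(calls = calls,
       histogram = hist,
       smoothed = data.frame(offset_tiles = grid, total = smoothedTotal))
}
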