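#' Surrogate predictor parameters
#'
#' Tunable settings for [scanSites] barrier strengths and for the
#' loop-extrusion surrogate predictor. These are fixture parameters that
#' give the screens a known mechanistic ground truth; they are not claims
#' about biology.
#'
#' Barrier strength is derived from the motif log-odds score and the GC
#' fraction of the `flankWindow` bp on either side of the motif window:
#' \itemize{
#'   \item `strengthTransform = "logistic"` (default):
#'     `strength = logistic((score - logisticMid)/logisticScale) *
#'     logistic((gc - flankMid)/flankScale)` — multiplicative core and flank
#'     factors, each saturating in (0,1).
#'   \item `strengthTransform = "linear"`:
#'     `strength = strengthScale * (score + flankCoef * nGC + strengthOffset)`
#'     with `nGC` the GC count in the flank windows — fully additive in
#'     per-position contributions, used to probe additivity of mutational
#'     effects.
#'   \item `strengthTransform = "saturating"`: logistic of the same additive
#'     raw value: `logistic((strengthScale*(score + flankCoef*nGC +
#'     strengthOffset) - satMid)/satScale)` — additive up to a saturating
#'     nonlinearity.
#' }
#'
#' Map construction: insulation subtracts `beta` times the barrier mass
#' strictly between two bins (floored at `floor`); each convergent barrier
#' pair adds a Gaussian dot of amplitude `gamma * s1 * s2 * exp(-d/d0)` at
#' the anchor pixel; maps are clipped to `clipRange` and smoothed with a 2-D
#' Gaussian of `smoothSigmaBins` bins. `shadeFrac`/`shadeDecay` optionally
#' spread a fraction of each barrier's mass geometrically in its pointing
#' direction (directional shading), giving co-oriented cassettes an
#' asymmetric insulation footprint; shading is off by default.
#'
#' @param threshold Log-odds scan threshold (bits vs uniform background).
#' @param strengthTransform One of `"logistic"`, `"linear"`, `"saturating"`.
#' @param logisticMid,logisticScale Midpoint/scale of the core logistic.
#' @param flankWindow Flank width in bp scored for GC on each side.
#' @param flankMid,flankScale Midpoint/scale of the GC-flank logistic.
#' @param flankCoef,strengthOffset,strengthScale Additive-mode coefficients.
#' @param satMid,satScale Saturating-mode logistic parameters.
#' @param beta Insulation depth per unit barrier mass (map units).
#' @param gamma Dot amplitude scale.
#' @param d0 Dot distance decay in bp.
#' @param dotSigmaBins Dot Gaussian width in bins.
#' @param smoothSigmaBins Final 2-D Gaussian smoothing width (0 = none).
#' @param floor Lower saturation of the insulation term (map units).
#' @param clipRange Map clip interval.
#' @param shadeFrac,shadeDecay Directional shading fraction and per-bin
#'   geometric decay (shading disabled when `shadeFrac = 0`).
#' @return Named list of parameters.
#' @export
surrogateParams <- function(threshold = 12,
                            strengthTransform = c("logistic", "linear", "saturating"),
                            logisticMid = 20, logisticScale = 2,
                            flankWindow = 15L, flankMid = 0.4, flankScale = 0.08,
                            flankCoef = 0.2, strengthOffset = 30, strengthScale = 1/60,
                            satMid = 1.05, satScale = 0.12,
                            beta = 0.25, gamma = 2, d0 = 3e5,
                            dotSigmaBins = 1.5, smoothSigmaBins = 1,
                            floor = -2, clipRange = c(-2, 2),
                            shadeFrac = 0, shadeDecay = 0.95) {
  list(threshold = threshold,
       strengthTransform = match.arg(strengthTransform),
       logisticMid = logisticMid, logisticScale = logisticScale,
       flankWindow = as.integer(flankWindow), flankMid = flankMid,
       flankScale = flankScale, flankCoef = flankCoef,
       strengthOffset = strengthOffset, strengthScale = strengthScale,
       satMid = satMid, satScale = satScale,
       beta = beta, gamma = gamma, d0 = d0,
       dotSigmaBins = dotSigmaBins, smoothSigmaBins = smoothSigmaBins,
       floor = floor, clipRange = clipRange,
       shadeFrac = shadeFrac, shadeDecay = shadeDecay)
}

.barrierStrength <- function(score, gcFrac, nGC, params) {
  switch(params$strengthTransform,
    logistic = .logistic((score - params$logisticMid) / params$logisticScale) *
      .logistic((gcFrac - params$flankMid) / params$flankScale),
    linear = params$strengthScale *
      (score + params$flankCoef * nGC + params$strengthOffset),
    saturating = .logistic((params$strengthScale *
      (score + params$flankCoef * nGC + params$strengthOffset) -
      params$satMid) / params$satScale)
  )
}

#' Scan a sequence for motif barriers
#'
#' Scores every window of both strands against a position probability
#' matrix (log2 odds vs uniform background), keeps windows at or above
#' `threshold`, and resolves overlaps greedily by score. Windows containing
#' N are skipped. Each retained hit is annotated with the GC fraction of
#' its `flankWindow`-bp flanks and a barrier strength derived from score
#' and flank GC via `params` (strength is monotone non-decreasing in the
#' log-odds score at fixed flanks).
#'
#' @param seq Character or `DNAString` sequence.
#' @param ppm 4 x L probability matrix (default the bundled CTCF motif).
#' @param threshold Log-odds threshold; defaults to `params$threshold`.
#' @param params See [surrogateParams].
#' @return data.frame with columns `start`, `end`, `mid` (1-based bp of the
#'   window midpoint), `strand` (`"+"`/`"-"`), `score`, `gcFlank`, `nGC`,
#'   `strength`, ordered by position. Empty (zero-row) when the sequence is
#'   shorter than the motif or nothing passes threshold.
#' @examples
#' s <- paste0(strrep("A", 50), motifConsensus(ctcfMotif()), strrep("A", 50))
#' scanSites(s)
#' @export
scanSites <- function(seq, ppm = ctcfMotif(), threshold = NULL,
                      params = surrogateParams()) {
  if (is.null(threshold)) threshold <- params$threshold
  s <- .asSeqChar(seq)
  e <- .encodeDNA(s)
  n <- length(e)
  L <- ncol(ppm)
  empty <- data.frame(start = integer(), end = integer(), mid = integer(),
                      strand = character(), score = numeric(),
                      gcFlank = numeric(), nGC = integer(),
                      strength = numeric())
  if (n < L) return(empty)
  lo <- .logOdds(ppm)
  m <- n - L + 1L

  strandScore <- function(mat) {
    sc <- numeric(m)
    for (k in seq_len(L)) sc <- sc + mat[, k][e[k:(k + m - 1L)]]
    sc # NA where any window base is N
  }
  scF <- strandScore(lo)
  scR <- strandScore(.revCompPPM(lo))

  fwHits <- which(!is.na(scF) & scF >= threshold)
  rvHits <- which(!is.na(scR) & scR >= threshold)
  hits <- data.frame(start = c(fwHits, rvHits),
                     strand = rep(c("+", "-"), c(length(fwHits), length(rvHits))))
  if (!nrow(hits)) return(empty)
  hits$score <- ifelse(hits$strand == "+", scF[hits$start], scR[hits$start])
  hits <- hits[order(-hits$score, hits$start, hits$strand), , drop = FALSE]

  occupied <- logical(n)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    win <- hits$start[i]:(hits$start[i] + L - 1L)
    if (!any(occupied[win])) {
      keep[i] <- TRUE
      occupied[win] <- TRUE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$end <- hits$start + L - 1L
  hits$mid <- hits$start + (L - 1L) %/% 2L

  fw <- params$flankWindow
  flankStats <- vapply(seq_len(nrow(hits)), function(i) {
    up <- e[max(1L, hits$start[i] - fw):max(0L, hits$start[i] - 1L)]
    if (hits$start[i] == 1L) up <- integer()
    dn <- if (hits$end[i] < n) e[(hits$end[i] + 1L):min(n, hits$end[i] + fw)] else integer()
    fl <- c(up, dn)
    ok <- !is.na(fl)
    c(gc = if (any(ok)) sum(fl[ok] == 2L | fl[ok] == 3L) / sum(ok) else 0.5,
      ngc = if (any(ok)) sum(fl[ok] == 2L | fl[ok] == 3L) else 0)
  }, numeric(2L))
  hits$gcFlank <- flankStats["gc", ]
  hits$nGC <- as.integer(flankStats["ngc", ])
  hits$strength <- .barrierStrength(hits$score, hits$gcFlank, hits$nGC, params)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("start", "end", "mid", "strand", "score", "gcFlank", "nGC", "strength")]
}

#' SurrogatePredictor: a mechanistic stand-in contact-map predictor
#'
#' Predicts log observed/expected contact maps from sequence through an
#' explicit loop-extrusion caricature: motif hits become extrusion barriers
#' whose summed strength between two bins depletes their contact
#' (insulation), and convergent barrier pairs add focal enrichment (dots).
#' The construction is deterministic, strand-symmetric by design, and cheap
#' enough to run thousands of predictions per minute, which makes every
#' perturbation procedure in the package testable against known ground
#' truth. Targets emulate cell types by scaling the insulation and dot
#' amplitudes.
#'
#' @slot windowBp Accepted sequence length in bp.
#' @slot binSize Bin width in bp.
#' @slot nBins Output map side length (`windowBp = nBins * binSize`).
#' @slot ppm The 4 x L scanning motif.
#' @slot params Parameter list from [surrogateParams].
#' @slot targets data.frame with columns `name`, `betaMult`, `gammaMult`.
#' @name SurrogatePredictor-class
#' @aliases SurrogatePredictor
#' @export
setClass("SurrogatePredictor",
  slots = c(windowBp = "integer", binSize = "integer", nBins = "integer",
            ppm = "matrix", params = "list", targets = "data.frame")
)

setValidity("SurrogatePredictor", function(object) {
  if (object@windowBp != object@nBins * object@binSize)
    return("windowBp must equal nBins * binSize")
  if (!all(c("name", "betaMult", "gammaMult") %in% names(object@targets)))
    return("targets needs columns name, betaMult, gammaMult")
  TRUE
})

#' @param windowBp,binSize,nBins Geometry; give any two, the third is
#'   derived (defaults mirror a 1,310,720 bp window of 640 x 2048 bp bins).
#' @param ppm Scanning motif (default [ctcfMotif]).
#' @param params [surrogateParams] list.
#' @param targets data.frame(name, betaMult, gammaMult); default two
#'   pseudo-cell-types at scale 1 and 0.9.
#' @return A `SurrogatePredictor`.
#' @rdname SurrogatePredictor-class
#' @export
surrogatePredictor <- function(windowBp = NULL, binSize = 2048L, nBins = NULL,
                               ppm = ctcfMotif(), params = surrogateParams(),
                               targets = NULL) {
  binSize <- .checkScalarInt(binSize, "binSize")
  if (is.null(nBins) && is.null(windowBp)) nBins <- 640L
  if (is.null(nBins)) nBins <- as.integer(windowBp / binSize)
  nBins <- .checkScalarInt(nBins, "nBins")
  if (is.null(windowBp)) windowBp <- nBins * binSize
  if (is.null(targets))
    targets <- data.frame(name = c("cellA", "cellB"),
                          betaMult = c(1, 0.9), gammaMult = c(1, 0.9))
  new("SurrogatePredictor", windowBp = as.integer(windowBp),
      binSize = binSize, nBins = nBins, ppm = .checkPPM(ppm),
      params = params, targets = targets)
}

#' @rdname predictContacts
#' @export
setMethod("windowSize", "SurrogatePredictor", function(object) object@windowBp)

#' @rdname mapValues
#' @export
setMethod("binSize", "SurrogatePredictor", function(x) x@binSize)

#' @rdname mapValues
#' @export
setMethod("nBins", "SurrogatePredictor", function(x) x@nBins)

#' @rdname predictContacts
#' @export
setMethod("targetNames", "SurrogatePredictor",
          function(object) object@targets$name)

setMethod("show", "SurrogatePredictor", function(object) {
  cat("SurrogatePredictor:", object@nBins, "bins x", object@binSize,
      "bp =", object@windowBp, "bp window\n")
  cat("  targets:", paste(object@targets$name, collapse = ", "),
      "| strength transform:", object@params$strengthTransform, "\n")
})

# Gaussian blur by banded row-normalised kernel matrix; symmetric maps stay
# symmetric and the edge renormalisation is flip-invariant.
.blurMatrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  K <- matrix(0, n, n)
  for (d in -r:r) {
    w <- exp(-d^2 / (2 * sigma^2))
    idx <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(idx, idx + d)] <- w else K[cbind(idx + abs(d), idx)] <- w
  }
  K / rowSums(K)
}

# per-bin barrier mass deposition, with optional one-sided geometric shading
.depositBarriers <- function(barriers, nb, binSizeBp, params) {
  b <- numeric(nb)
  if (!nrow(barriers)) return(b)
  bins <- ((barriers$mid - 1L) %/% binSizeBp) + 1L
  lam <- params$shadeFrac
  for (i in seq_len(nrow(barriers))) {
    s <- barriers$strength[i]
    k <- bins[i]
    if (lam <= 0) {
      b[k] <- b[k] + s
      next
    }
    b[k] <- b[k] + s * (1 - lam)
    dir <- if (barriers$strand[i] == "+") 1L else -1L
    q <- params$shadeDecay
    t <- 1L
    w <- lam * (1 - q)
    while (w > 1e-9 * s && t <= nb) {
      kk <- k + dir * t
      if (kk >= 1L && kk <= nb) b[kk] <- b[kk] + s * w
      t <- t + 1L
      w <- w * q
    }
  }
  b
}

#' @describeIn predictContacts surrogate prediction: scan barriers, build
#'   insulation from the barrier mass strictly between bins, add Gaussian
#'   dots for convergent pairs, clip, smooth. Deterministic given sequence
#'   and parameters; `predictContacts(revComp(s))` equals the
#'   coordinate-flipped forward prediction.
#' @export
setMethod("predictContacts", "SurrogatePredictor", function(object, seq, ...) {
  s <- .asSeqChar(seq)
  if (nchar(s) != object@windowBp)
    stop("predictor contract violation: sequence length ", nchar(s),
         " != window ", object@windowBp)
  p <- object@params
  barriers <- scanSites(s, object@ppm, p$threshold, p)
  nb <- object@nBins
  b <- .depositBarriers(barriers, nb, object@binSize, p)

  cs <- cumsum(b)
  I <- row(diag(nb)); J <- col(diag(nb))
  lo <- pmin(I, J); hi <- pmax(I, J)
  # barrier mass strictly between bins lo and hi
  S <- matrix(0, nb, nb)
  inner <- hi - lo >= 2L
  S[inner] <- cs[hi[inner] - 1L] - cs[lo[inner]]

  # dot anchors: forward barrier upstream of reverse barrier
  dotBump <- matrix(0, nb, nb)
  if (nrow(barriers) && p$gamma != 0) {
    fw <- barriers[barriers$strand == "+", , drop = FALSE]
    rv <- barriers[barriers$strand == "-", , drop = FALSE]
    if (nrow(fw) && nrow(rv)) {
      sig <- p$dotSigmaBins
      r <- ceiling(4 * sig)
      off <- -r:r
      kern <- exp(-outer(off^2, off^2, "+") / (2 * sig^2))
      bins <- function(x) ((x - 1L) %/% object@binSize) + 1L
      for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
        if (fw$mid[i] >= rv$mid[j]) next
        d <- rv$mid[j] - fw$mid[i]
        amp <- fw$strength[i] * rv$strength[j] * exp(-d / p$d0) # gamma applied per target
        bi <- bins(fw$mid[i]); bj <- bins(rv$mid[j])
        ri <- (bi + off); rj <- (bj + off)
        oki <- ri >= 1L & ri <= nb; okj <- rj >= 1L & rj <= nb
        dotBump[ri[oki], rj[okj]] <- dotBump[ri[oki], rj[okj]] +
          amp * kern[oki, okj, drop = FALSE]
        if (bi != bj)
          dotBump[rj[okj], ri[oki]] <- dotBump[rj[okj], ri[oki]] +
            amp * t(kern[oki, okj, drop = FALSE])
      }
    }
  }

  K <- if (p$smoothSigmaBins > 0) .blurMatrix(nb, p$smoothSigmaBins) else NULL
  out <- lapply(seq_len(nrow(object@targets)), function(t) {
    tg <- object@targets[t, ]
    V <- pmax(-p$beta * tg$betaMult * S, p$floor) +
      p$gamma * tg$gammaMult * dotBump
    V <- pmin(pmax(V, p$clipRange[1L]), p$clipRange[2L])
    if (!is.null(K)) V <- K %*% V %*% t(K)
    ContactMap(V, binSize = object@binSize, clipRange = p$clipRange)
  })
  names(out) <- object@targets$name
  out
})
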