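# Virtual-insertion experiment designs: flank sweeps, core x flank
# compatibility with SVD, saturation/pairwise mutagenesis, multi-site
# grammar and dot/boundary scenarios.

# Precompute reference maps per background x model so screens that score
# hundreds of layouts on the same backgrounds don't re-predict them.
.refCache <- function(backgrounds, predictors) {
  lapply(backgrounds, function(bg)
    lapply(predictors, predictContacts, seq = bg))
}

.reducedInsertion <- function(bgChar, layout, predictors, method, cache) {
  vals <- numeric(0)
  for (bi in seq_along(bgChar)) {
    withIns <- assembleInsertion(bgChar[bi], layout)
    for (mi in seq_along(predictors)) {
      altMaps <- predictContacts(predictors[[mi]], withIns)
      vals <- c(vals, .scoreAgainst(cache[[bi]][[mi]], altMaps, method))
    }
  }
  mean(vals)
}

.prepBackgrounds <- function(backgrounds) {
  if (is(backgrounds, "DNAStringSet")) backgrounds <- as.character(backgrounds)
  vapply(backgrounds, .asSeqChar, character(1L), USE.NAMES = FALSE)
}

#' Flank-length sweep for a single site
#'
#' Inserts one site into each background with symmetric flanks of
#' increasing length (0 bp = core only) and returns the reduced insertion
#' score per length. The site must carry genomic flanks at least as long as
#' `max(lengths)` on both sides.
#'
#' @param site A [CTCFSiteSeq-class] with sufficient flanks.
#' @param predictor Predictor or named list of predictors.
#' @param backgrounds Neutral background sequences.
#' @param lengths Flank lengths in bp (default 0:35).
#' @param method Passed to [mapDifferenceScore].
#' @return data.frame with columns `flank_bp` and `score`.
#' @export
flankSweep <- function(site, predictor, backgrounds, lengths = 0:35,
                       method = c("sqrt_sum", "mse")) {
  method <- match.arg(method)
  bg <- .prepBackgrounds(backgrounds)
  predictors <- .asPredictorList(predictor)
  cache <- .refCache(bg, predictors)
  scores <- vapply(lengths, function(l) {
    trimmed <- .truncateFlanks(site, l)
    .reducedInsertion(bg, insertionLayout(trimmed), predictors, method, cache)
  }, numeric(1L))
  data.frame(flank_bp = as.integer(lengths), score = scores)
}

#' CoreFlankMatrix: pairwise core x flank insertion scores with SVD
#'
#' The matrix `M[i, j]` of insertion scores for synthetic sites combining
#' core `i` with flank pair `j`, factorised as `M = U D V'`. The rank-1
#' reconstruction `D[1] * U[,1] %o% V[,1]` captures the multiplicative
#' structure; signs are fixed so the mean of each first singular vector is
#' non-negative. Diagonal entries are the cognate (genomic) combinations
#' when cores and flanks are supplied in matched order.
#'
#' @slot M Score matrix.
#' @slot coreIds,flankIds Identifiers.
#' @slot u,v First left/right singular vectors (sign-fixed).
#' @slot d Singular values.
#' @slot rank1 Rank-1 reconstruction.
#' @slot residual Frobenius norm of `M - rank1`.
#' @name CoreFlankMatrix-class
#' @aliases CoreFlankMatrix
#' @export
setClass("CoreFlankMatrix",
  slots = c(M = "matrix", coreIds = "character", flankIds = "character",
            u = "numeric", v = "numeric", d = "numeric",
            rank1 = "matrix", residual = "numeric")
)

#' @param M Numeric score matrix (cores x flanks).
#' @param coreIds,flankIds Optional identifiers.
#' @return A `CoreFlankMatrix` with SVD factors computed.
#' @rdname CoreFlankMatrix-class
#' @export
coreFlankMatrix <- function(M, coreIds = NULL, flankIds = NULL) {
  if (is.null(coreIds)) coreIds <- rownames(M) %||% paste0("core", seq_len(nrow(M)))
  if (is.null(flankIds)) flankIds <- colnames(M) %||% paste0("flank", seq_len(ncol(M)))
  sv <- svd(M)
  u <- sv$u[, 1L]; v <- sv$v[, 1L]
  # fix signs: flip the pair so mean(u) >= 0; score matrices are
  # non-negative, so mean(v) then comes out non-negative too
  if (mean(u) < 0) { u <- -u; v <- -v }
  rank1 <- sv$d[1L] * (u %o% v)
  new("CoreFlankMatrix", M = M, coreIds = coreIds, flankIds = flankIds,
      u = u, v = v, d = sv$d, rank1 = rank1,
      residual = sqrt(sum((M - rank1)^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname CoreFlankMatrix-class
#' @param x A `CoreFlankMatrix`.
#' @export
cfScores <- function(x) x@M

#' @rdname CoreFlankMatrix-class
#' @export
cfRankOne <- function(x) x@rank1

#' @rdname CoreFlankMatrix-class
#' @export
cfCoreStrengths <- function(x) stats::setNames(x@u, x@coreIds)

#' @rdname CoreFlankMatrix-class
#' @export
cfFlankStrengths <- function(x) stats::setNames(x@v, x@flankIds)

#' @rdname CoreFlankMatrix-class
#' @export
cfCognate <- function(x) diag(x@M)

setMethod("show", "CoreFlankMatrix", function(object) {
  cat("CoreFlankMatrix:", nrow(object@M), "cores x", ncol(object@M), "flanks\n")
  cat(sprintf("  rank-1 residual (Frobenius): %.4g (relative %.4g)\n",
              object@residual, object@residual / sqrt(sum(object@M^2))))
})

#' Core x flank compatibility screen
#'
#' Scores every combination of `n` cores with `n` flank pairs by virtual
#' insertion and factorises the resulting matrix by SVD. An exactly
#' multiplicative predictor yields an exactly rank-1 matrix.
#'
#' @param cores List of [CTCFSiteSeq-class] (their cores are used).
#' @param flanks List of [CTCFSiteSeq-class] (their flanks are used); must
#'   match `cores` in length, index-matched for cognate pairs.
#' @param predictor Predictor or named list.
#' @param backgrounds Neutral backgrounds.
#' @param method Passed to [mapDifferenceScore].
#' @return A [CoreFlankMatrix-class].
#' @export
coreFlankScreen <- function(cores, flanks, predictor, backgrounds,
                            method = c("sqrt_sum", "mse")) {
  method <- match.arg(method)
  if (length(cores) != length(flanks))
    stop("invalid screen: core and flank lists differ in length")
  bg <- .prepBackgrounds(backgrounds)
  predictors <- .asPredictorList(predictor)
  cache <- .refCache(bg, predictors)
  n <- length(cores)
  M <- matrix(NA_real_, n, n,
              dimnames = list(vapply(cores, function(s) s@id, character(1L)),
                              vapply(flanks, function(s) s@id, character(1L))))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    combo <- ctcfSite(cores[[i]]@core, flanks[[j]]@flankUp,
                      flanks[[j]]@flankDown,
                      id = paste0(cores[[i]]@id, "x", flanks[[j]]@id))
    M[i, j] <- .reducedInsertion(bg, insertionLayout(combo), predictors,
                                 method, cache)
  }
  coreFlankMatrix(M)
}

#' MutationScoreTable: single and pairwise mutagenesis scores
#'
#' Holds mutagenesis results over the 49-bp region formed by a 19-bp core
#' with 15-bp flanks on either side. `single` is the 49 x 4 matrix of
#' mutation scores (insertion score of the mutant minus the unperturbed
#' site; reference bases are exactly 0). `pairwise` holds, for each
#' position pair, the average over all 3 x 3 substitution combinations and
#' over sites; `additive` is the matching sum of averaged single-position
#' scores. Same-position pairs are excluded (NA).
#'
#' @slot region Reference 49-bp sequence (of the first site).
#' @slot single 49 x 4 matrix (columns A,C,G,T).
#' @slot pairwise,additive 49 x 49 symmetric matrices (NA off the scored
#'   positions).
#' @slot positions Integer positions (1-49) actually scored.
#' @name MutationScoreTable-class
#' @aliases MutationScoreTable
#' @export
setClass("MutationScoreTable",
  slots = c(region = "character", single = "matrix", pairwise = "matrix",
            additive = "matrix", positions = "integer")
)

setMethod("show", "MutationScoreTable", function(object) {
  cat("MutationScoreTable over", nchar(object@region), "bp;",
      length(object@positions), "positions scored\n")
})

# site -> the canonical 49-bp mutagenesis region (15 + 19 + 15)
.mutRegion <- function(site) {
  s <- .truncateFlanks(site, 15L)
  siteSequence(s)
}

.siteFromRegion <- function(region, id) {
  ctcfSite(substr(region, 16L, 34L),
           flankUp = substr(region, 1L, 15L),
           flankDown = substr(region, 35L, 49L), id = id)
}

#' Single-nucleotide saturation mutagenesis
#'
#' Scores every substitution at every position of the 49-bp core-plus-flank
#' region as insertion(mutant) - insertion(reference). Reference-base
#' entries are exactly 0.
#'
#' @param site [CTCFSiteSeq-class] with >= 15 bp flanks.
#' @param predictor Predictor or named list.
#' @param backgrounds Neutral backgrounds.
#' @param positions Positions (1-49) to mutate; default all.
#' @param method Passed to [mapDifferenceScore].
#' @return 49 x 4 numeric matrix (columns A,C,G,T), rows outside
#'   `positions` are NA except the implicit reference zeros.
#' @export
saturationMutagenesis <- function(site, predictor, backgrounds,
                                  positions = 1:49,
                                  method = c("sqrt_sum", "mse")) {
  method <- match.arg(method)
  bg <- .prepBackgrounds(backgrounds)
  predictors <- .asPredictorList(predictor)
  cache <- .refCache(bg, predictors)
  region <- .mutRegion(site)
  refScore <- .reducedInsertion(bg, insertionLayout(.siteFromRegion(region, site@id)),
                                predictors, method, cache)
  bases <- c("A", "C", "G", "T")
  out <- matrix(NA_real_, 49L, 4L, dimnames = list(NULL, bases))
  for (p in positions) {
    refBase <- substr(region, p, p)
    for (b in bases) {
      if (b == refBase) { out[p, b] <- 0; next }
      mutRegion <- region
      substr(mutRegion, p, p) <- b
      sc <- .reducedInsertion(bg, insertionLayout(.siteFromRegion(mutRegion, site@id)),
                              predictors, method, cache)
      out[p, b] <- sc - refScore
    }
  }
  attr(out, "region") <- region
  attr(out, "refScore") <- refScore
  out
}

#' Pairwise mutagenesis with additive expectation
#'
#' For each pair of distinct positions, scores all 3 x 3 combinations of
#' non-reference substitutions, averages them (and averages over sites),
#' and compares with the additive expectation: the sum of the two averaged
#' single-position mutation scores.
#'
#' @param sites List of [CTCFSiteSeq-class] (non-empty).
#' @param predictor Predictor or named list.
#' @param backgrounds Neutral backgrounds.
#' @param positions Positions (1-49) to pair; default all 49 (1,176 pairs
#'   x 9 substitutions per site - consider a subset for quick screens).
#' @param method Passed to [mapDifferenceScore].
#' @return A [MutationScoreTable-class].
#' @export
pairwiseMutagenesis <- function(sites, predictor, backgrounds,
                                positions = 1:49,
                                method = c("sqrt_sum", "mse")) {
  method <- match.arg(method)
  if (!length(sites)) stop("invalid input: empty site list")
  bg <- .prepBackgrounds(backgrounds)
  predictors <- .asPredictorList(predictor)
  cache <- .refCache(bg, predictors)
  bases <- c("A", "C", "G", "T")
  positions <- sort(unique(as.integer(positions)))

  singleSum <- matrix(0, 49L, 4L, dimnames = list(NULL, bases))
  pairSum <- matrix(0, 49L, 49L)
  nSites <- length(sites)

  for (site in sites) {
    region <- .mutRegion(site)
    refScore <- .reducedInsertion(bg,
      insertionLayout(.siteFromRegion(region, site@id)),
      predictors, method, cache)
    scoreMut <- function(reg) {
      .reducedInsertion(bg, insertionLayout(.siteFromRegion(reg, site@id)),
                        predictors, method, cache) - refScore
    }
    sgl <- matrix(0, 49L, 4L, dimnames = list(NULL, bases))
    for (p in positions) {
      refBase <- substr(region, p, p)
      for (b in setdiff(bases, refBase)) {
        mutReg <- region
        substr(mutReg, p, p) <- b
        sgl[p, b] <- scoreMut(mutReg)
      }
    }
    singleSum <- singleSum + sgl
    for (ii in seq_along(positions)) for (jj in seq_along(positions)) {
      if (jj <= ii) next
      p <- positions[ii]; q <- positions[jj]
      refP <- substr(region, p, p); refQ <- substr(region, q, q)
      vals <- numeric(0)
      for (bp_ in setdiff(bases, refP)) for (bq in setdiff(bases, refQ)) {
        mutReg <- region
        substr(mutReg, p, p) <- bp_
        substr(mutReg, q, q) <- bq
        vals <- c(vals, scoreMut(mutReg))
      }
      pairSum[p, q] <- pairSum[p, q] + mean(vals)
    }
  }

  single <- singleSum / nSites
  # averaged single mutation score per position (mean over the 3 non-ref bases)
  refRegion <- .mutRegion(sites[[1L]])
  posMean <- vapply(1:49, function(p) {
    refBase <- substr(refRegion, p, p)
    mean(single[p, setdiff(bases, refBase)])
  }, numeric(1L))

  pairwise <- matrix(NA_real_, 49L, 49L)
  additive <- matrix(NA_real_, 49L, 49L)
  for (ii in seq_along(positions)) for (jj in seq_along(positions)) {
    if (jj <= ii) next
    p <- positions[ii]; q <- positions[jj]
    pairwise[p, q] <- pairwise[q, p] <- pairSum[p, q] / nSites
    additive[p, q] <- additive[q, p] <- posMean[p] + posMean[q]
  }

  new("MutationScoreTable", region = refRegion, single = single,
      pairwise = pairwise, additive = additive, positions = positions)
}

#' Multi-site grammar screen
#'
#' Scores cassette insertions over a grid of site counts, spacings and
#' orientation strings. With `orientations = NULL` each `n` uses a tandem
#' rightward cassette; otherwise the orientation strings determine the
#' number of sites and `nSites` is ignored.
#'
#' @param site [CTCFSiteSeq-class] used for every element.
#' @param predictor Predictor or named list.
#' @param backgrounds Neutral backgrounds.
#' @param nSites Integer vector of cassette sizes (default 1:6).
#' @param spacings Integer vector of core-to-core gaps in bp (default 180).
#' @param orientations Optional character vector of orientation strings
#'   (e.g. `c(">>", "<<", "><", "<>")`).
#' @param method Passed to [mapDifferenceScore].
#' @return data.frame with columns `n_sites`, `spacing_bp`, `orientation`,
#'   `score`.
#' @export
grammarScreen <- function(site, predictor, backgrounds, nSites = 1:6,
                          spacings = 180L, orientations = NULL,
                          method = c("sqrt_sum", "mse")) {
  method <- match.arg(method)
  bg <- .prepBackgrounds(backgrounds)
  predictors <- .asPredictorList(predictor)
  cache <- .refCache(bg, predictors)
  if (is.null(orientations)) {
    grid <- expand.grid(orientation = vapply(nSites, function(n) strrep(">", n),
                                             character(1L)),
                        spacing = spacings, stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(orientation = orientations, spacing = spacings,
                        stringsAsFactors = FALSE)
  }
  grid$n_sites <- nchar(grid$orientation)
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    lay <- insertionLayout(site, orientations = grid$orientation[i],
                           spacingBp = grid$spacing[i])
    .reducedInsertion(bg, lay, predictors, method, cache)
  }, numeric(1L))
  data.frame(n_sites = grid$n_sites, spacing_bp = as.integer(grid$spacing),
             orientation = grid$orientation, score = grid$score)
}

#' Dot versus boundary scenario scores for one site
#'
#' Two canonical two-site layouts probe feature formation: a "boundary"
#' (divergent `<>` pair, 180 bp apart) scored by the global insertion
#' score, and a "dot" (convergent `><` pair, 400 kb apart by default)
#' scored locally by [dotScore] at the expected anchor pixel of the
#' insertion map (averaged over backgrounds, targets and models).
#'
#' @param site [CTCFSiteSeq-class] (30-bp flanks recommended).
#' @param predictor Predictor or named list; its window must accommodate
#'   the dot spacing.
#' @param backgrounds Neutral backgrounds.
#' @param boundarySpacing Divergent-pair gap in bp (default 180).
#' @param dotSpacing Convergent-pair gap in bp (default 400,000).
#' @param method Passed to [mapDifferenceScore].
#' @return List with `boundary` (insertion score), `dot` (anchor dot
#'   score), and `anchors` (anchor bins of the dot layout).
#' @export
dotBoundaryScenarios <- function(site, predictor, backgrounds,
                                 boundarySpacing = 180L, dotSpacing = 400000L,
                                 method = c("sqrt_sum", "mse")) {
  method <- match.arg(method)
  bg <- .prepBackgrounds(backgrounds)
  predictors <- .asPredictorList(predictor)
  win <- windowSize(predictors[[1L]])
  span <- 2L * 19L + dotSpacing
  if (span + 2L * (nchar(site@flankUp) + 40L) >= win)
    stop("invalid configuration: predictor window too small for ",
         dotSpacing, " bp site separation")
  cache <- .refCache(bg, predictors)

  boundary <- .reducedInsertion(bg,
    insertionLayout(site, orientations = "<>", spacingBp = boundarySpacing),
    predictors, method, cache)

  dotLayout <- insertionLayout(site, orientations = "><", spacingBp = dotSpacing)
  n <- nchar(bg[1L])
  first <- (n - span) %/% 2L + 1L
  mid1 <- first + 9L
  mid2 <- first + 19L + dotSpacing + 9L
  bsz <- binSize(predictors[[1L]])
  anchors <- c(((mid1 - 1L) %/% bsz) + 1L, ((mid2 - 1L) %/% bsz) + 1L)

  dots <- numeric(0)
  for (bi in seq_along(bg)) {
    withIns <- assembleInsertion(bg[bi], dotLayout)
    for (mi in seq_along(predictors)) {
      maps <- predictContacts(predictors[[mi]], withIns)
      dots <- c(dots, vapply(maps, dotScore, numeric(1L),
                             i = anchors[1L], j = anchors[2L]))
    }
  }
  list(boundary = boundary, dot = mean(dots), anchors = anchors)
}
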