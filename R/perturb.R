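# Disruption-by-permutation and insertion scoring.

.asPredictorList <- function(predictor) {
  if (is.list(predictor) && !is(predictor, "SurrogatePredictor")) {
    if (is.null(names(predictor)))
      names(predictor) <- paste0("model", seq_along(predictor))
    predictor
  } else {
    list(model0 = predictor)
  }
}

#' Permute a sub-sequence in place
#'
#' Replaces the span `[start, end]` (1-based, inclusive) with a uniform
#' random permutation of its own residues, keeping the rest of the sequence
#' fixed. Nucleotide composition of the span is preserved exactly.
#'
#' @param seq Character or `DNAString`.
#' @param start,end 1-based inclusive span bounds.
#' @param seed Optional RNG seed.
#' @return Character scalar.
#' @export
permuteSpan <- function(seq, start, end, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .asSeqChar(seq)
  n <- nchar(s)
  if (!(is.numeric(start) && is.numeric(end) && start >= 1 && end <= n && start <= end))
    stop("invalid span: need 1 <= start <= end <= ", n)
  span <- substr(s, start, end)
  perm <- paste(sample(strsplit(span, "")[[1L]]), collapse = "")
  paste0(substr(s, 1L, start - 1L), perm, substr(s, end + 1L, n))
}

# score all target maps of one prediction against a reference prediction
.scoreAgainst <- function(refMaps, altMaps, method) {
  vapply(names(refMaps), function(tn)
    mapDifferenceScore(refMaps[[tn]], altMaps[[tn]], method = method),
    numeric(1L))
}

#' Genomic disruption score of a span
#'
#' Permutes a span of the input sequence in its genomic context and scores
#' the change between predicted maps before and after. One score per
#' permutation x target x model is collected in a [ScorePanel-class] whose
#' declared averaging order is permutations, then targets, then models.
#'
#' @param seq Window-length genomic sequence.
#' @param start,end Span to permute (1-based inclusive, within the window).
#' @param predictor A predictor or named list of predictors (model axis).
#' @param nPermutations Number of independent permutations (default 1).
#' @param method Passed to [mapDifferenceScore].
#' @param seed Optional RNG seed.
#' @param subject Subject label stored in the panel.
#' @return A [ScorePanel-class]; `reduceScores` gives the disruption score.
#' @export
genomicDisruption <- function(seq, start, end, predictor, nPermutations = 1L,
                              method = c("sqrt_sum", "mse"), seed = NULL,
                              subject = "span") {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  s <- .asSeqChar(seq)
  predictors <- .asPredictorList(predictor)
  refMaps <- lapply(predictors, predictContacts, seq = s)
  tn <- names(refMaps[[1L]])
  a <- array(NA_real_,
             dim = c(1L, nPermutations, length(tn), length(predictors)),
             dimnames = list(subject = subject,
                             permutation = paste0("perm", seq_len(nPermutations)),
                             target = tn, model = names(predictors)))
  for (pi in seq_len(nPermutations)) {
    mut <- permuteSpan(s, start, end)
    for (mi in seq_along(predictors)) {
      altMaps <- predictContacts(predictors[[mi]], mut)
      a[1L, pi, , mi] <- .scoreAgainst(refMaps[[mi]], altMaps, method)
    }
  }
  ScorePanel(a, reduction = c("permutation", "target", "model"))
}

#' Virtual insertion score of a layout
#'
#' Assembles the layout into each background sequence and scores the change
#' between the background prediction and the prediction after insertion,
#' per background x target x model. The declared averaging order is
#' backgrounds, then targets, then models.
#'
#' @param backgrounds Character vector / `DNAStringSet` of window-length
#'   neutral background sequences (typically ten).
#' @param layout An [InsertionLayout-class] (empty layouts score 0).
#' @param predictor A predictor or named list of predictors.
#' @param method Passed to [mapDifferenceScore].
#' @param subject Subject label stored in the panel.
#' @return A [ScorePanel-class]; `reduceScores` gives the insertion score.
#' @export
insertionScore <- function(backgrounds, layout, predictor,
                           method = c("sqrt_sum", "mse"), subject = "layout") {
  method <- match.arg(method)
  if (is(backgrounds, "DNAStringSet")) {
    backgrounds <- as.character(backgrounds)
  }
  backgrounds <- vapply(backgrounds, .asSeqChar, character(1L), USE.NAMES = FALSE)
  predictors <- .asPredictorList(predictor)
  tn <- targetNames(predictors[[1L]])
  if (is.null(tn)) tn <- names(predictContacts(predictors[[1L]], backgrounds[1L]))
  a <- array(NA_real_,
             dim = c(1L, length(backgrounds), length(tn), length(predictors)),
             dimnames = list(subject = subject,
                             background = paste0("bg", seq_along(backgrounds)),
                             target = tn, model = names(predictors)))
  for (bi in seq_along(backgrounds)) {
    withIns <- assembleInsertion(backgrounds[bi], layout)
    for (mi in seq_along(predictors)) {
      refMaps <- predictContacts(predictors[[mi]], backgrounds[bi])
      altMaps <- predictContacts(predictors[[mi]], withIns)
      a[1L, bi, , mi] <- .scoreAgainst(refMaps, altMaps, method)
    }
  }
  ScorePanel(a, reduction = c("background", "target", "model"))
}

#' Tiled disruption around a center position
#'
#' Permutes consecutive non-overlapping tiles spanning `halfSpan` bp either
#' side of `centerBp` and records the disruption score of each tile. The
#' tile grid is anchored at the center, so with the defaults there are
#' exactly 44 tiles at signed offsets -45,056 ... +43,008 bp (offsets are
#' tile left edges relative to the center).
#'
#' @param seq Window-length sequence.
#' @param centerBp 1-based center coordinate (e.g. a boundary position).
#' @param predictor A predictor or named list.
#' @param halfSpan Half-width of the tiled region in bp.
#' @param tile Tile width in bp; `halfSpan` must be a multiple.
#' @param nPermutations Permutations per tile (default 1).
#' @param method Passed to [mapDifferenceScore].
#' @param seed Optional RNG seed.
#' @return data.frame with columns `offset` (bp, tile left edge relative to
#'   center) and `score` (panel-reduced disruption).
#' @export
tiledDisruption <- function(seq, centerBp, predictor, halfSpan = 45056L,
                            tile = 2048L, nPermutations = 1L,
                            method = c("sqrt_sum", "mse"), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  s <- .asSeqChar(seq)
  n <- nchar(s)
  if (halfSpan %% tile != 0L)
    stop("halfSpan must be an integer multiple of the tile size")
  offsets <- seq.int(-halfSpan, halfSpan - tile, by = tile)
  if (centerBp - halfSpan < 1L || centerBp + halfSpan - 1L > n)
    stop("invalid placement: tiles extend beyond the sequence window")
  predictors <- .asPredictorList(predictor)
  refMaps <- lapply(predictors, predictContacts, seq = s)
  scores <- vapply(offsets, function(off) {
    st <- centerBp + off
    vals <- numeric(0)
    for (pi in seq_len(nPermutations)) {
      mut <- permuteSpan(s, st, st + tile - 1L)
      for (mi in seq_along(predictors)) {
        altMaps <- predictContacts(predictors[[mi]], mut)
        vals <- c(vals, .scoreAgainst(refMaps[[mi]], altMaps, method))
      }
    }
    mean(vals)
  }, numeric(1L))
  data.frame(offset = offsets, score = scores)
}
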