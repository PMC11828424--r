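# Synthetic fixtures: genomes with planted motif sites of known strength
# and contact maps with planted boundaries/dots. Pure functions of
# (spec, seed) so reruns are byte-identical.

#' Synthesise a genome with planted motif sites
#'
#' Draws a random background from a base composition and writes 19-bp core
#' motifs (with optional GC-tuned 15-bp flanks) at stated positions and
#' orientations. The returned truth table lists every planted element.
#'
#' @param length Sequence length in bp.
#' @param sites Optional data.frame with columns `position` (1-based core
#'   start), `orientation` (`"+"`/`"-"`), `core` (19-bp string), and
#'   optionally `flankGC` (target GC level of the 15-bp flanks, in `[0,1]`;
#'   NA = leave background) and `label`.
#' @param composition Base probabilities (A, C, G, T).
#' @param flankBp Flank length written on each side when `flankGC` is set.
#' @param seed Optional RNG seed.
#' @return List with `sequence` (character) and `truth` (data.frame).
#' @export
synthGenome <- function(length, sites = NULL,
                        composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                        flankBp = 15L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .randomDNA(length, composition)
  if (is.null(sites) || !nrow(sites)) {
    return(list(sequence = s,
                truth = data.frame(position = integer(), orientation = character(),
                                   core = character(), label = character())))
  }
  if (is.null(sites$flankGC)) sites$flankGC <- NA_real_
  if (is.null(sites$label)) sites$label <- paste0("site", seq_len(nrow(sites)))
  # overlap check over full extents (core plus optional flanks)
  ext <- cbind(sites$position - ifelse(is.na(sites$flankGC), 0L, flankBp),
               sites$position + 18L + ifelse(is.na(sites$flankGC), 0L, flankBp))
  ord <- order(ext[, 1L])
  if (any(ext[ord, 1L][-1L] <= ext[ord, 2L][-nrow(ext)]))
    stop("invalid spec: planted sites overlap")
  if (any(ext[, 1L] < 1L) || any(ext[, 2L] > length))
    stop("invalid spec: planted site outside sequence")
  chars <- strsplit(s, "")[[1L]]
  for (i in seq_len(nrow(sites))) {
    core <- toupper(sites$core[i])
    if (nchar(core) != 19L) stop("invalid spec: cores must be 19 bp")
    unit <- core
    offset <- 0L
    if (!is.na(sites$flankGC[i])) {
      gc <- sites$flankGC[i]
      comp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      unit <- paste0(.randomDNA(flankBp, comp), core, .randomDNA(flankBp, comp))
      offset <- flankBp
    }
    if (sites$orientation[i] == "-") unit <- revComp(unit)
    st <- sites$position[i] - offset
    chars[st:(st + nchar(unit) - 1L)] <- strsplit(unit, "")[[1L]]
  }
  list(sequence = paste(chars, collapse = ""),
       truth = data.frame(position = sites$position,
                          orientation = sites$orientation,
                          core = toupper(sites$core), flankGC = sites$flankGC,
                          label = sites$label))
}

#' A motif-free background sequence
#'
#' Draws a random sequence and erases every motif hit of the predictor's
#' scanning motif (replacing hit windows with A's) until a rescan finds
#' nothing, yielding a deterministic, fully featureless background. Useful
#' when exactness matters more than sequence realism; use
#' [generateBackground] for shuffle-derived backgrounds.
#'
#' @param predictor A [SurrogatePredictor-class] (supplies window, motif,
#'   threshold).
#' @param composition Base probabilities.
#' @param seed Optional RNG seed.
#' @return Character scalar of length `windowSize(predictor)`.
#' @export
cleanBackground <- function(predictor,
                            composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .randomDNA(windowSize(predictor), composition)
  repeat {
    hits <- scanSites(s, predictor@ppm, predictor@params$threshold,
                      predictor@params)
    if (!nrow(hits)) return(s)
    for (i in seq_len(nrow(hits))) {
      substr(s, hits$start[i], hits$end[i]) <-
        strrep("A", hits$end[i] - hits$start[i] + 1L)
    }
  }
}

#' Synthesise a contact map with planted features
#'
#' Builds a symmetric log observed/expected map from a zero baseline:
#' boundaries deplete every cell straddling the boundary bin (cells `(i,j)`
#' with `i < b <= j`) by their depth, dots add Gaussian spots of stated
#' amplitude at their anchors, and optional symmetric Gaussian noise is
#' added before clipping.
#'
#' @param nBins Map side length.
#' @param boundaries Optional data.frame with columns `bin` (the boundary
#'   sits between `bin - 1` and `bin`) and `depth` (> 0, map units).
#' @param dots Optional data.frame with columns `i`, `j`, `amplitude` and
#'   optionally `sigma` (bins, default 1).
#' @param noiseSd Additive Gaussian noise sd (symmetrised).
#' @param binSize Bin size in bp.
#' @param clip Clip interval.
#' @param seed Optional RNG seed.
#' @return A [ContactMap-class].
#' @export
synthMap <- function(nBins, boundaries = NULL, dots = NULL, noiseSd = 0,
                     binSize = 2048L, clip = c(-2, 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- .checkScalarInt(nBins, "nBins")
  V <- matrix(0, n, n)
  I <- row(V); J <- col(V)
  if (!is.null(boundaries) && nrow(boundaries)) {
    if (any(boundaries$bin < 2L | boundaries$bin > n))
      stop("invalid spec: boundary bin outside map")
    for (r in seq_len(nrow(boundaries))) {
      b <- boundaries$bin[r]
      straddle <- (pmin(I, J) < b) & (pmax(I, J) >= b)
      V[straddle] <- V[straddle] - boundaries$depth[r]
    }
  }
  if (!is.null(dots) && nrow(dots)) {
    if (is.null(dots$sigma)) dots$sigma <- 1
    if (any(dots$i < 1L | dots$i > n | dots$j < 1L | dots$j > n))
      stop("invalid spec: dot anchor outside map")
    for (r in seq_len(nrow(dots))) {
      g <- exp(-((I - dots$i[r])^2 + (J - dots$j[r])^2) / (2 * dots$sigma[r]^2))
      gt <- exp(-((I - dots$j[r])^2 + (J - dots$i[r])^2) / (2 * dots$sigma[r]^2))
      V <- V + dots$amplitude[r] * (g + gt) / (1 + (dots$i[r] == dots$j[r]))
    }
  }
  if (noiseSd > 0) {
    E <- matrix(stats::rnorm(n * n, sd = noiseSd), n, n)
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    V <- V + E
  }
  V <- pmin(pmax(V, clip[1L]), clip[2L])
  ContactMap(V, binSize = binSize, clipRange = clip)
}
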