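#' Specification for neutral background generation
#'
#' Neutral backgrounds are produced by repeatedly shuffling a genomic
#' sequence in fixed-size chunks until its predicted map is flat enough.
#' Defaults follow the standard recipe: 8-bp chunks, signal-strength
#' acceptance threshold 35 (defined at the 640-bin map size and rescaled as
#' `(nBins/640)^2` for smaller maps), at most 20 shuffling iterations.
#'
#' @param chunkBp Chunk size in bp (>= 1).
#' @param threshold Acceptance threshold on the target-averaged map signal
#'   strength, quoted at the 640-bin reference size.
#' @param maxIterations Iteration cap; exceeding it is a reported rejection.
#' @param seed Optional RNG seed recorded with each generated background.
#' @return A `BackgroundSpec` object.
#' @name BackgroundSpec-class
#' @aliases BackgroundSpec
#' @export
setClass("BackgroundSpec",
  slots = c(chunkBp = "integer", threshold = "numeric",
            maxIterations = "integer", seed = "integer")
)

setValidity("BackgroundSpec", function(object) {
  if (object@chunkBp < 1L) return("chunkBp must be >= 1")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  TRUE
})

#' @rdname BackgroundSpec-class
#' @export
backgroundSpec <- function(chunkBp = 8L, threshold = 35,
                           maxIterations = 20L, seed = NA_integer_) {
  new("BackgroundSpec", chunkBp = as.integer(chunkBp),
      threshold = as.numeric(threshold),
      maxIterations = as.integer(maxIterations), seed = as.integer(seed))
}

#' Shuffle a sequence in fixed-size chunks
#'
#' Partitions the sequence into consecutive non-overlapping chunks of
#' `chunkBp` bases (a final partial chunk is kept intact as its own unit)
#' and permutes the chunk order uniformly at random. Length and the
#' multiset of full chunks are preserved; `chunkBp = 1` permutes single
#' nucleotides, `chunkBp >= nchar(seq)` degenerates to the identity.
#'
#' @param seq Character or `DNAString`.
#' @param chunkBp Chunk size in bp.
#' @param seed Optional RNG seed for reproducibility.
#' @return Shuffled sequence as a character scalar.
#' @export
chunkShuffle <- function(seq, chunkBp = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .asSeqChar(seq)
  chunkBp <- .checkScalarInt(chunkBp, "chunkBp")
  n <- nchar(s)
  if (chunkBp >= n) return(s)
  starts <- seq.int(1L, n, by = chunkBp)
  ends <- pmin(starts + chunkBp - 1L, n)
  chunks <- substring(s, starts, ends)
  paste(chunks[sample.int(length(chunks))], collapse = "")
}

#' Generate a neutral background sequence
#'
#' Applies [chunkShuffle] to the candidate repeatedly (each iteration
#' re-shuffles the current candidate) and accepts the first candidate whose
#' target-averaged [mapSignalStrength] under `predictor` falls below the
#' effective threshold. Exceeding `maxIterations` is a reported rejection,
#' not an error. The spec threshold is quoted at the 640-bin reference map
#' and rescaled by `(nBins(predictor)/640)^2`.
#'
#' @param seq Genomic input sequence of length `windowSize(predictor)`.
#' @param predictor Any object honouring the [predictContacts] contract.
#' @param spec A [backgroundSpec].
#' @return List with elements `sequence` (character, the last candidate),
#'   `accepted` (logical), `iterations` (count used), `signal` (last
#'   signal strength), `effectiveThreshold`, and `seed`.
#' @export
generateBackground <- function(seq, predictor, spec = backgroundSpec()) {
  s <- .asSeqChar(seq)
  if (!is.na(spec@seed)) set.seed(spec@seed)
  eff <- spec@threshold * (nBins(predictor) / 640)^2
  candidate <- s
  signal <- NA_real_
  for (it in seq_len(spec@maxIterations)) {
    candidate <- chunkShuffle(candidate, spec@chunkBp)
    maps <- predictContacts(predictor, candidate)
    signal <- mean(vapply(maps, mapSignalStrength, numeric(1L)))
    if (signal < eff) {
      return(list(sequence = candidate, accepted = TRUE, iterations = it,
                  signal = signal, effectiveThreshold = eff,
                  seed = spec@seed))
    }
  }
  list(sequence = candidate, accepted = FALSE,
       iterations = spec@maxIterations, signal = signal,
       effectiveThreshold = eff, seed = spec@seed)
}
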