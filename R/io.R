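# Interchange I/O: FASTA through Biostrings, BED through rtracklayer
# (0-based half-open on disk, 1-based GRanges in memory).

#' Read and write genomic intervals as BED
#'
#' Thin wrappers over `rtracklayer::import`/`export` that keep the
#' package's interval currency a [GenomicRanges::GRanges] (1-based
#' closed in memory; conversion to BED's 0-based half-open happens at the
#' file boundary).
#'
#' @param path BED file path.
#' @param gr A `GRanges` (name/score/strand columns are written if set).
#' @return `readRegionsBed` returns a `GRanges`; `writeRegionsBed`
#'   invisibly returns `path`.
#' @export
readRegionsBed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED I/O")
  rtracklayer::import(path, format = "BED")
}

#' @rdname readRegionsBed
#' @export
writeRegionsBed <- function(gr, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED I/O")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @importFrom Biostrings readDNAStringSet
#' @export
readFastaSequences <- function(path) Biostrings::readDNAStringSet(path)

#' Write DNA sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @importFrom Biostrings writeXStringSet
#' @return Invisibly, `path`.
#' @export
writeFastaSequences <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) {
    nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(unname(seqs))
    names(seqs) <- nm
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
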