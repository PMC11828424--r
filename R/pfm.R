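# Position frequency / probability matrix handling. A PPM is represented
# as a plain 4 x L numeric matrix with rownames A,C,G,T and columns summing
# to one; nothing heavier is needed for scanning and logo work.

.checkPPM <- function(ppm) {
  if (!is.matrix(ppm) || nrow(ppm) != 4L)
    stop("PPM must be a 4 x L matrix with rows A,C,G,T")
  if (is.null(rownames(ppm))) rownames(ppm) <- c("A", "C", "G", "T")
  if (any(ppm < 0)) stop("PPM entries must be non-negative")
  cs <- colSums(ppm)
  if (any(abs(cs - 1) > 1e-6)) stop("PPM columns must sum to 1")
  ppm
}

#' Read a position frequency matrix
#'
#' `readJasparPFM` parses plain JASPAR text (`>ID name` header then four
#' `A [ ... ]` rows); `readMemePFM` parses the minimal MEME motif format
#' (first motif in the file). Both return a position probability matrix:
#' counts plus a pseudocount, normalised per column.
#'
#' @param path File path.
#' @param pseudocount Added to every count before normalisation.
#' @return 4 x L numeric matrix (rows A,C,G,T; columns sum to 1).
#' @export
readJasparPFM <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  rows <- lapply(lines[1:4], function(ln) {
    stripped <- sub("^\\s*[ACGTacgt]", "", ln)
    as.numeric(regmatches(stripped,
                          gregexpr("[0-9]+(\\.[0-9]+)?", stripped))[[1L]])
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- toupper(substr(trimws(lines[1:4]), 1L, 1L))
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  .normalisePFM(counts, pseudocount)
}

#' @rdname readJasparPFM
#' @export
readMemePFM <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  i <- grep("^letter-probability matrix", lines)
  if (!length(i)) stop("no letter-probability matrix block found")
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[i[1L]]))
  block <- lines[(i[1L] + 1L):(i[1L] + w)]
  probs <- t(vapply(block, function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]),
                    numeric(4L), USE.NAMES = FALSE))
  counts <- t(probs) # MEME rows are positions, columns A C G T
  rownames(counts) <- c("A", "C", "G", "T")
  .normalisePFM(counts, pseudocount)
}

.normalisePFM <- function(counts, pseudocount) {
  m <- counts + pseudocount
  m <- sweep(m, 2L, colSums(m), "/")
  .checkPPM(m)
}

#' Bundled CTCF core motif
#'
#' The 19-bp CTCF position probability matrix (JASPAR MA0139.1 counts,
#' shipped as plain text with the package) used as the default motif for
#' scanning and for fixture construction.
#'
#' @param pseudocount Passed to [readJasparPFM].
#' @return 4 x 19 probability matrix.
#' @export
ctcfMotif <- function(pseudocount = 0.5) {
  readJasparPFM(system.file("extdata", "MA0139.1.jaspar",
                            package = "foldGrammar", mustWork = TRUE),
                pseudocount = pseudocount)
}

#' Consensus string of a probability matrix
#'
#' @param ppm 4 x L probability matrix.
#' @return Character scalar, the per-column argmax base.
#' @export
motifConsensus <- function(ppm) {
  ppm <- .checkPPM(ppm)
  paste(rownames(ppm)[apply(ppm, 2L, which.max)], collapse = "")
}

# log2 odds versus uniform background
.logOdds <- function(ppm) log2(.checkPPM(ppm) / 0.25)

# reverse-complement a 4 x L matrix (swap A/T and C/G, reverse columns)
.revCompPPM <- function(m) m[4:1, ncol(m):1, drop = FALSE]
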