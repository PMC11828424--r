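# Internal sequence helpers. Sequences are handled as upper-case character
# scalars over {A,C,G,T,N}; Biostrings objects are accepted at every user
# boundary and coerced here.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @importFrom Biostrings DNAString DNAStringSet
.asSeqChar <- function(seq) {
  if (is(seq, "DNAString")) {
    s <- as.character(seq)
  } else if (is(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence, got a set of length ", length(seq))
    s <- as.character(seq[[1L]])
  } else if (is.character(seq) && length(seq) == 1L) {
    s <- toupper(seq)
  } else {
    stop("sequence must be a character scalar, DNAString, or length-1 DNAStringSet")
  }
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0L)
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1L]]), collapse = ","))
  s
}

# Integer encoding A=1 C=2 G=3 T=4, N -> NA
.encodeDNA <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
}

.decodeDNA <- function(e) {
  out <- c("A", "C", "G", "T")[e]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

#' Reverse complement of a character DNA sequence
#'
#' Thin convenience wrapper around [Biostrings::reverseComplement] that
#' accepts and returns plain character scalars (N is preserved).
#'
#' @param seq Character scalar or `DNAString`.
#' @return Character scalar.
#' @importFrom Biostrings reverseComplement
#' @export
revComp <- function(seq) {
  s <- .asSeqChar(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# GC fraction among non-N positions of an encoded vector; `ifEmpty` is
# returned when no scorable base is present.
.gcFraction <- function(e, ifEmpty = 0.5) {
  ok <- !is.na(e)
  if (!any(ok)) return(ifEmpty)
  sum(e[ok] == 2L | e[ok] == 3L) / sum(ok)
}

.logistic <- function(x) 1 / (1 + exp(-x))

.checkScalarInt <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(name, " must be a single integer >= ", min)
  as.integer(x)
}

# Draw a random DNA string of length n from a base composition
.randomDNA <- function(n, composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  p <- composition / sum(composition)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}
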