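# Motif and flank statistics: PPMs/logos, weighted Jensen-Shannon
# difference, k-mer enrichment, positional GC and partial correlations.

.splitSeqs <- function(seqs) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("alignment error: sequences differ in length")
  list(mat = do.call(rbind, strsplit(seqs, "")), L = L)
}

#' Build a position probability matrix from aligned sequences
#'
#' Column-wise base frequencies with a pseudocount, normalised so each
#' column sums to 1. N residues are ignored in the counts.
#'
#' @param seqs Character vector or `DNAStringSet` of equal-length sequences.
#' @param pseudocount Added to each base count per column (default 0.5).
#' @return 4 x L probability matrix (rows A,C,G,T).
#' @export
buildPPM <- function(seqs, pseudocount = 0.5) {
  sp <- .splitSeqs(seqs)
  if (nrow(sp$mat) < 1L) stop("need at least one sequence")
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(sp$L), function(j)
    vapply(bases, function(b) sum(sp$mat[, j] == b), numeric(1L)),
    numeric(4L))
  rownames(counts) <- bases
  .normalisePFM(counts, pseudocount)
}

#' Per-position information content in bits
#'
#' @param ppm 4 x L probability matrix.
#' @return Numeric vector of `2 - H` bits per position, in `[0, 2]`.
#' @export
motifInformation <- function(ppm) {
  ppm <- .checkPPM(ppm)
  apply(ppm, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Weighted Jensen-Shannon difference between two motifs
#'
#' Per position, the Jensen-Shannon divergence (in bits) between the two
#' base distributions, with signed per-symbol contributions weighted by the
#' normalised probability differences: symbol `s` contributes
#' `JSD * (P_s - Q_s) / sum(|P - Q|)` (0 when the distributions are equal).
#' Increases in the first motif are positive; swapping the motifs negates
#' contributions but leaves totals unchanged.
#'
#' @param P,Q 4 x L probability matrices of equal width.
#' @return List with `total` (length-L numeric, bits) and `contributions`
#'   (4 x L signed matrix whose absolute column sums equal `total`).
#' @export
weightedJSD <- function(P, Q) {
  P <- .checkPPM(P); Q <- .checkPPM(Q)
  if (ncol(P) != ncol(Q)) stop("incompatible motifs: widths differ")
  L <- ncol(P)
  total <- numeric(L)
  contrib <- matrix(0, 4L, L, dimnames = dimnames(P))
  for (j in seq_len(L)) {
    p <- P[, j]; q <- Q[, j]
    jsd <- .shannon((p + q) / 2) - (.shannon(p) + .shannon(q)) / 2
    total[j] <- jsd
    denom <- sum(abs(p - q))
    if (denom > 0) contrib[, j] <- jsd * (p - q) / denom
  }
  list(total = total, contributions = contrib)
}

#' k-mer presence enrichment between strong and weak sequence sets
#'
#' For every k-mer, compares the fraction of sequences containing it at
#' least once between the two sets. Significance is assessed against a
#' pooled label-permutation null (the exchangeability null for a group
#' difference) with a two-sided permutation p-value, Bonferroni-corrected
#' by the `4^k` k-mers tested.
#'
#' @param strong,weak Character vectors (or `DNAStringSet`) of sequences.
#' @param k k-mer size (2 or 3 typical).
#' @param nBoot Number of permutation draws (default 100,000).
#' @param alpha Family-wise significance level before correction.
#' @param seed Optional RNG seed.
#' @return data.frame with one row per k-mer: `kmer`, `fracStrong`,
#'   `fracWeak`, `difference`, `p`, `significant`.
#' @export
kmerEnrichment <- function(strong, weak, k = 2L, nBoot = 1e5L, alpha = 0.05,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(strong, "DNAStringSet")) strong <- as.character(strong)
  if (is(weak, "DNAStringSet")) weak <- as.character(weak)
  if (!length(strong) || !length(weak)) stop("both sets must be non-empty")
  k <- .checkScalarInt(k, "k")
  if (k > min(nchar(c(strong, weak)))) stop("invalid k: exceeds sequence length")
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                             stringsAsFactors = FALSE)[, k:1, drop = FALSE],
                 1L, paste, collapse = "")
  pooled <- c(toupper(strong), toupper(weak))
  n1 <- length(strong); n <- length(pooled)
  # presence matrix: sequence x kmer
  Pm <- vapply(kmers, function(km) grepl(km, pooled, fixed = TRUE),
               logical(n)) * 1
  obs <- colMeans(Pm[seq_len(n1), , drop = FALSE]) -
    colMeans(Pm[(n1 + 1L):n, , drop = FALSE])

  # permutation null in blocks to bound memory
  exceed <- numeric(length(kmers))
  done <- 0L
  blk <- 2000L
  tot <- colSums(Pm)
  while (done < nBoot) {
    b <- min(blk, nBoot - done)
    Lbl <- matrix(0, n, b)
    for (col in seq_len(b)) Lbl[sample.int(n, n1), col] <- 1
    s1 <- crossprod(Pm, Lbl) / n1              # kmer x b, strong fraction
    s0 <- (tot - s1 * n1) / (n - n1)
    nullDiff <- s1 - s0
    exceed <- exceed + rowSums(abs(nullDiff) >= abs(obs) - 1e-12)
    done <- done + b
  }
  p <- (exceed + 1) / (nBoot + 1)
  alphaCorr <- alpha / length(kmers)
  data.frame(kmer = kmers,
             fracStrong = colMeans(Pm[seq_len(n1), , drop = FALSE]),
             fracWeak = colMeans(Pm[(n1 + 1L):n, , drop = FALSE]),
             difference = obs, p = p, significant = p < alphaCorr,
             row.names = NULL)
}

#' Positional GC fraction of aligned sequences
#'
#' @param seqs Equal-length sequences.
#' @return Numeric vector: per position, the fraction of G or C among
#'   non-N residues.
#' @export
positionalGC <- function(seqs) {
  sp <- .splitSeqs(seqs)
  vapply(seq_len(sp$L), function(j) {
    col <- sp$mat[, j]
    ok <- col != "N"
    if (!any(ok)) return(NA_real_)
    sum(col[ok] %in% c("G", "C")) / sum(ok)
  }, numeric(1L))
}

#' Partial correlations of features with a target
#'
#' For each feature, the correlation between the residuals of the target
#' and of that feature after regressing both on all remaining features
#' (ordinary least squares). Also returns the plain pairwise correlation
#' matrix of features and target.
#'
#' @param features Numeric matrix (subjects x features) with column names.
#' @param target Numeric vector of length `nrow(features)`.
#' @return List with `partial` (named vector) and `pairwise` (correlation
#'   matrix including the target as last row/column).
#' @export
partialCorrelation <- function(features, target) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (is.null(colnames(features))) colnames(features) <- paste0("x", seq_len(p))
  if (nrow(features) <= p + 2L)
    stop("need more subjects than features + 2")
  if (any(apply(features, 2L, stats::sd) == 0))
    stop("constant feature column")
  if (qr(cbind(1, features))$rank < p + 1L)
    stop("collinearity: feature matrix is rank deficient")
  partial <- vapply(seq_len(p), function(j) {
    others <- features[, -j, drop = FALSE]
    if (ncol(others) == 0L) return(stats::cor(features[, j], target))
    rj <- stats::resid(stats::lm(features[, j] ~ others))
    rt <- stats::resid(stats::lm(target ~ others))
    stats::cor(rj, rt)
  }, numeric(1L))
  names(partial) <- colnames(features)
  all <- cbind(features, target = target)
  list(partial = partial, pairwise = stats::cor(all))
}
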