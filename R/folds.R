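#' Partition genome regions into cross-validation folds
#'
#' Jointly assigns regions connected by whole-genome alignment to the same
#' fold, so that orthologous sequence never leaks between training and test
#' sets. Regions are vertices; each supplied pair (regions with substantial
#' aligning sequence, the >500 kb criterion being applied upstream by the
#' caller) is an edge. Connected components are assigned greedily, largest
#' first, to the fold with the smallest running total of bp; ties go to the
#' lowest fold index.
#'
#' @param regions A [GenomicRanges::GRanges] with unique `names`, or a
#'   data.frame with columns `id`, `chrom`, `start`, `end` (bp, half-open
#'   BED-style for the data.frame input).
#' @param alignedPairs Two-column matrix or data.frame of region ids; may
#'   have zero rows.
#' @param nFolds Number of folds (default 8).
#' @return Named integer vector mapping region id to fold index in
#'   `1:nFolds`. Any two regions connected (transitively) by pairs share a
#'   fold.
#' @examples
#' regs <- data.frame(id = LETTERS[1:4], chrom = "chr1",
#'                    start = c(0, 5e6, 1e7, 1.5e7) , end = c(5e6, 1e7, 1.5e7, 2e7))
#' partitionFolds(regs, data.frame(a = "A", b = "B"), nFolds = 2)
#' @importFrom igraph graph_from_data_frame components
#' @export
partitionFolds <- function(regions, alignedPairs = NULL, nFolds = 8L) {
  nFolds <- .checkScalarInt(nFolds, "nFolds")
  if (is(regions, "GRanges")) {
    ids <- names(regions)
    if (is.null(ids)) stop("GRanges regions must be named with region ids")
    bp <- GenomicRanges::width(regions)
  } else {
    ids <- as.character(regions$id)
    if (any(regions$start >= regions$end) || any(regions$start < 0))
      stop("malformed regions: need 0 <= start < end")
    bp <- regions$end - regions$start
  }
  if (anyDuplicated(ids)) stop("region ids must be unique")
  names(bp) <- ids

  if (is.null(alignedPairs) || NROW(alignedPairs) == 0L) {
    edges <- data.frame(from = character(), to = character())
  } else {
    edges <- data.frame(from = as.character(alignedPairs[[1L]]),
                        to = as.character(alignedPairs[[2L]]))
    unknown <- setdiff(c(edges$from, edges$to), ids)
    if (length(unknown))
      stop("aligned pair references unknown region(s): ",
           paste(unknown, collapse = ","))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]

  compBp <- tapply(bp, comp, sum)
  # deterministic order: decreasing bp, ties by smallest member id
  minId <- tapply(ids, comp, function(x) min(x))
  ord <- order(-compBp, minId)
  foldBp <- numeric(nFolds)
  foldOf <- integer(length(compBp))
  names(foldOf) <- names(compBp)
  for (ci in names(compBp)[ord]) {
    f <- which.min(foldBp) # ties -> lowest index
    foldOf[ci] <- f
    foldBp[f] <- foldBp[f] + compBp[ci]
  }
  out <- foldOf[as.character(comp)]
  names(out) <- ids
  out
}
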