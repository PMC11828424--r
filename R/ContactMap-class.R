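#' ContactMap: a square log observed/expected contact matrix
#'
#' The universal currency of all scores in the package: an `n x n` matrix of
#' log observed/expected contact values at a fixed genomic bin size, with an
#' optional per-bin missing mask and a clip range that bounds all finite
#' non-missing values. Maps are symmetric (within floating tolerance) on
#' their non-missing cells. A missing bin masks its whole row and column.
#'
#' @slot values Numeric `n x n` matrix.
#' @slot binSize Integer, bin width in bp (default 2048).
#' @slot missingBins Logical vector of length `n`; `TRUE` marks a missing bin.
#' @slot clipRange Numeric length-2 increasing interval containing all
#'   non-missing values (default `c(-2, 2)`).
#'
#' @examples
#' cm <- ContactMap(matrix(0, 8, 8), binSize = 2048L)
#' mapSignalStrength(cm)
#' @name ContactMap-class
#' @aliases ContactMap
#' @export
setClass("ContactMap",
  slots = c(
    values = "matrix",
    binSize = "integer",
    missingBins = "logical",
    clipRange = "numeric"
  )
)

setValidity("ContactMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) != ncol(v)) return("contact matrix must be square")
  n <- nrow(v)
  if (length(object@binSize) != 1L || object@binSize < 1L)
    return("binSize must be a single positive integer")
  if (length(object@missingBins) != n)
    return("missingBins must have one entry per bin")
  cr <- object@clipRange
  if (length(cr) != 2L || !all(is.finite(cr)) || cr[1L] > cr[2L])
    return("clipRange must be an increasing length-2 numeric")
  ok <- !object@missingBins
  sub <- v[ok, ok, drop = FALSE]
  fin <- sub[is.finite(sub)]
  tol <- 1e-8
  if (length(fin) && (min(fin) < cr[1L] - tol || max(fin) > cr[2L] + tol))
    return("non-missing values fall outside the clip range")
  if (length(fin) == length(sub) && length(sub) &&
      max(abs(sub - t(sub))) > 1e-6)
    return("contact matrix is not symmetric on non-missing cells")
  TRUE
})

#' @param values Numeric square matrix of log observed/expected values.
#' @param binSize Bin width in bp.
#' @param missingBins Optional logical per-bin mask (default: none missing).
#' @param clipRange Clip interval; values are checked (not clipped) against it.
#' @return A `ContactMap` object.
#' @rdname ContactMap-class
#' @export
ContactMap <- function(values, binSize = 2048L, missingBins = NULL,
                       clipRange = c(-2, 2)) {
  if (is.null(missingBins)) missingBins <- rep(FALSE, nrow(values))
  new("ContactMap", values = values, binSize = as.integer(binSize),
      missingBins = missingBins, clipRange = as.numeric(clipRange))
}

#' @rdname mapValues
#' @export
setMethod("mapValues", "ContactMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("binSize", "ContactMap", function(x) x@binSize)

#' @rdname mapValues
#' @export
setMethod("nBins", "ContactMap", function(x) nrow(x@values))

#' @rdname mapValues
#' @export
setMethod("missingBins", "ContactMap", function(x) x@missingBins)

#' @rdname mapValues
#' @export
setMethod("clipRange", "ContactMap", function(x) x@clipRange)

setMethod("show", "ContactMap", function(object) {
  n <- nBins(object)
  cat("ContactMap:", n, "x", n, "bins @", object@binSize, "bp",
      sprintf("(%.1f kb window)\n", n * object@binSize / 1000))
  cat("  clip range: [", object@clipRange[1L], ",", object@clipRange[2L], "]",
      " missing bins:", sum(object@missingBins), "\n")
})

# logical matrix of usable cells (both bins non-missing)
.okCells <- function(map) {
  ok <- !missingBins(map)
  outer(ok, ok, "&")
}

#' Predicted map signal strength
#'
#' Sum of squared values over all non-missing cells of a contact map. Used
#' as the flatness criterion when generating neutral background sequences:
#' featureless maps have near-zero signal strength.
#'
#' @param x A [ContactMap-class].
#' @return Non-negative numeric scalar.
#' @examples
#' mapSignalStrength(ContactMap(matrix(c(1, -1, -1, 1), 2), clipRange = c(-2, 2)))
#' @export
setGeneric("mapSignalStrength", function(x) standardGeneric("mapSignalStrength"))

#' @rdname mapSignalStrength
#' @export
setMethod("mapSignalStrength", "ContactMap", function(x) {
  ok <- .okCells(x)
  if (!any(ok)) stop("all cells of the map are missing")
  sum(mapValues(x)[ok]^2)
})

#' Difference score between two contact maps
#'
#' Quantifies the change between predicted maps before and after a sequence
#' perturbation. `sqrt_sum` (the default, and the definition behind both
#' disruption and insertion scores) is the square root of the sum of squared
#' per-cell differences; `mse` is the mean squared difference. Cells missing
#' in either map are excluded; the two maps must agree in shape, bin size
#' and missing mask.
#'
#' @param ref,alt [ContactMap-class] objects of identical geometry.
#' @param method `"sqrt_sum"` or `"mse"`.
#' @return Non-negative numeric scalar; 0 iff the maps are equal on
#'   non-missing cells. Symmetric in its arguments.
#' @export
mapDifferenceScore <- function(ref, alt, method = c("sqrt_sum", "mse")) {
  method <- match.arg(method)
  stopifnot(is(ref, "ContactMap"), is(alt, "ContactMap"))
  if (nBins(ref) != nBins(alt) || binSize(ref) != binSize(alt))
    stop("maps are incompatible: shape or bin size differ")
  if (!identical(missingBins(ref), missingBins(alt)))
    stop("maps are incompatible: missing masks differ")
  ok <- .okCells(ref)
  d <- (mapValues(ref) - mapValues(alt))[ok]
  switch(method,
    sqrt_sum = sqrt(sum(d^2)),
    mse = mean(d^2)
  )
}

#' Read and write contact maps as plain text
#'
#' Contact maps are stored as tab-separated matrix text with a small comment
#' header carrying the bin size, clip range and missing-bin indices, so maps
#' survive round trips without binary containers.
#'
#' @param x A [ContactMap-class].
#' @param path File path.
#' @return `readContactMap` returns a [ContactMap-class];
#'   `writeContactMap` invisibly returns `path`.
#' @export
writeContactMap <- function(x, path) {
  stopifnot(is(x, "ContactMap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# foldGrammar ContactMap v1",
    paste0("# bin_size=", binSize(x)),
    paste0("# clip_range=", paste(clipRange(x), collapse = ",")),
    paste0("# missing_bins=", paste(which(missingBins(x)), collapse = ","))
  ), con)
  write.table(format(mapValues(x), digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writeContactMap
#' @export
readContactMap <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^# ", key, "="), "", ln[1L])
  }
  bs <- as.integer(get("bin_size"))
  cr <- as.numeric(strsplit(get("clip_range"), ",")[[1L]])
  mbStr <- get("missing_bins")
  body <- lines[!grepl("^#", lines)]
  vals <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  mb <- rep(FALSE, nrow(vals))
  if (!is.na(mbStr) && nzchar(mbStr))
    mb[as.integer(strsplit(mbStr, ",")[[1L]])] <- TRUE
  ContactMap(vals, binSize = bs, missingBins = mb, clipRange = cr)
}
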