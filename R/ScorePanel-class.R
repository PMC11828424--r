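#' ScorePanel: a score tensor with declared averaging semantics
#'
#' Perturbation scores are indexed by subject (the site, span or layout
#' scored) and by named replication axes such as `permutation` or
#' `background`, `target` (predictor output / cell type) and `model`
#' (predictor in an ensemble). `reduceScores` averages over the reduction
#' axes in their declared order, leaving one score per subject. With a
#' single entry per subject the reduced score equals that entry.
#'
#' @slot scores Numeric array whose dimnames carry axis names; the first
#'   axis must be `subject`.
#' @slot reduction Character vector of axis names in averaging order.
#' @name ScorePanel-class
#' @aliases ScorePanel
#' @export
setClass("ScorePanel",
  slots = c(scores = "array", reduction = "character")
)

setValidity("ScorePanel", function(object) {
  dn <- dimnames(object@scores)
  axes <- names(dn)
  if (is.null(axes) || axes[1L] != "subject")
    return("scores must have named dimnames with 'subject' first")
  if (!all(object@reduction %in% axes[-1L]))
    return("reduction axes must name non-subject dimensions")
  if (!setequal(object@reduction, axes[-1L]))
    return("every non-subject axis must appear in the reduction order")
  TRUE
})

#' @param scores Named-dimension numeric array (first axis `subject`).
#' @param reduction Averaging order; defaults to the non-subject axes in
#'   array order.
#' @return A `ScorePanel`.
#' @rdname ScorePanel-class
#' @export
ScorePanel <- function(scores, reduction = NULL) {
  axes <- names(dimnames(scores))
  if (is.null(axes))
    stop("scores must have named dimnames with 'subject' first")
  if (is.null(reduction)) reduction <- setdiff(axes, "subject")
  new("ScorePanel", scores = scores, reduction = reduction)
}

#' @rdname reduceScores
#' @export
setMethod("scoreArray", "ScorePanel", function(panel) panel@scores)

#' @rdname reduceScores
#' @export
setMethod("reduceScores", "ScorePanel", function(panel) {
  a <- panel@scores
  for (ax in panel@reduction) {
    axes <- names(dimnames(a))
    keep <- which(axes != ax)
    dn <- dimnames(a)[keep]
    a <- apply(a, keep, mean)
    # apply() drops to a vector when one axis remains; restore names
    if (is.null(dim(a))) {
      a <- array(a, dim = lengths(dn), dimnames = dn)
    } else {
      dimnames(a) <- dn
    }
  }
  out <- as.numeric(a)
  names(out) <- dimnames(a)[["subject"]]
  out
})

setMethod("show", "ScorePanel", function(object) {
  d <- dim(object@scores)
  axes <- names(dimnames(object@scores))
  cat("ScorePanel:", paste(paste0(axes, "=", d), collapse = " x "), "\n")
  cat("  reduction order:", paste(object@reduction, collapse = " -> "), "\n")
})
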