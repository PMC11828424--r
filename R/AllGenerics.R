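#' @include foldGrammar-package.R
NULL

#' Matrix of contact values
#'
#' Accessors for the [ContactMap-class] container and for predictor objects.
#'
#' @param x A `ContactMap` (or, for `binSize`/`nBins`, a predictor).
#' @return `mapValues` the numeric matrix, `binSize` the bin width in bp,
#'   `nBins` the number of bins per side, `missingBins` the logical per-bin
#'   mask, `clipRange` the two-element clip interval.
#' @aliases binSize nBins missingBins clipRange
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname mapValues
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname mapValues
#' @export
setGeneric("missingBins", function(x) standardGeneric("missingBins"))

#' @rdname mapValues
#' @export
setGeneric("clipRange", function(x) standardGeneric("clipRange"))

#' Predict contact maps from a DNA sequence
#'
#' The predictor contract: any object with a `predictContacts` method maps a
#' fixed-length DNA sequence to one [ContactMap-class] per output target.
#' Everything downstream of prediction is predictor-agnostic, so adapters for
#' external trained models only need to implement this generic together with
#' `windowSize`, `binSize`, `nBins` and `targetNames`.
#'
#' @param object A predictor, e.g. a [SurrogatePredictor-class].
#' @param seq A DNA sequence (`character` or [Biostrings::DNAString]) whose
#'   length equals `windowSize(object)`.
#' @param ... Additional arguments for methods.
#' @return A named list of [ContactMap-class] objects, one per target.
#' @export
setGeneric("predictContacts", function(object, seq, ...)
  standardGeneric("predictContacts"))

#' @rdname predictContacts
#' @export
setGeneric("windowSize", function(object) standardGeneric("windowSize"))

#' @rdname predictContacts
#' @export
setGeneric("targetNames", function(object) standardGeneric("targetNames"))

#' Reduce a score panel to one score per subject
#'
#' Averages the panel tensor over its reduction axes in the declared order
#' (the order is recorded because non-linear reductions would not commute;
#' the default mean reduction does).
#'
#' @param panel A [ScorePanel-class].
#' @return Named numeric vector, one reduced score per subject.
#' @export
setGeneric("reduceScores", function(panel) standardGeneric("reduceScores"))

#' @rdname reduceScores
#' @export
setGeneric("scoreArray", function(panel) standardGeneric("scoreArray"))
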