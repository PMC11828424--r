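#' CTCFSiteSeq: a core motif with its flanking sequences
#'
#' A 19-bp core recognition sequence together with up- and downstream
#' flanking sequence (0-35 bp each) and, optionally, the genomic locus it
#' was taken from. Flanks may not contain N under the default filter.
#'
#' @slot core 19-bp character.
#' @slot flankUp,flankDown Character flanks (5' and 3' of the core on the
#'   given strand).
#' @slot id Identifier.
#' @name CTCFSiteSeq-class
#' @aliases CTCFSiteSeq
#' @export
setClass("CTCFSiteSeq",
  slots = c(core = "character", flankUp = "character",
            flankDown = "character", id = "character")
)

setValidity("CTCFSiteSeq", function(object) {
  if (nchar(object@core) != 19L) return("core must be exactly 19 bp")
  if (grepl("[^ACGT]", object@core)) return("core must contain only A,C,G,T")
  if (grepl("[^ACGT]", paste0(object@flankUp, object@flankDown)))
    return("flanks may not contain N or non-ACGT characters")
  TRUE
})

#' @param core 19-bp core sequence.
#' @param flankUp,flankDown Flanking sequences (possibly empty).
#' @param id Identifier (default "site").
#' @return A `CTCFSiteSeq`.
#' @rdname CTCFSiteSeq-class
#' @export
ctcfSite <- function(core, flankUp = "", flankDown = "", id = "site") {
  new("CTCFSiteSeq", core = toupper(core), flankUp = toupper(flankUp),
      flankDown = toupper(flankDown), id = id)
}

#' @rdname CTCFSiteSeq-class
#' @param x A `CTCFSiteSeq`.
#' @export
siteSequence <- function(x) paste0(x@flankUp, x@core, x@flankDown)

setMethod("show", "CTCFSiteSeq", function(object) {
  cat("CTCFSiteSeq", object@id, ": ",
      nchar(object@flankUp), "bp | ", object@core, " | ",
      nchar(object@flankDown), "bp\n", sep = "")
})

# truncate flanks symmetrically to `len` bp (taking the bases adjacent to
# the core)
.truncateFlanks <- function(site, len) {
  fu <- site@flankUp; fd <- site@flankDown
  if (nchar(fu) < len || nchar(fd) < len)
    stop("site ", site@id, " has insufficient flanking sequence for ", len, " bp")
  ctcfSite(site@core,
           flankUp = substr(fu, nchar(fu) - len + 1L, nchar(fu)),
           flankDown = substr(fd, 1L, len),
           id = site@id)
}

#' InsertionLayout: placement rules for one or more sites
#'
#' An ordered list of (site, orientation) elements with a fixed spacing
#' between successive cores (gap between one core's end and the next
#' core's start; flanks occupy the gap). Orientation `">"` inserts the
#' core+flank unit on the given strand, `"<"` inserts its reverse
#' complement (flanks travel with the core). The cassette is centered in
#' the window unless explicit anchor offsets are given.
#'
#' @slot sites List of [CTCFSiteSeq-class].
#' @slot orientations Character vector of `">"`/`"<"`.
#' @slot spacingBp Gap between successive core end and core start (bp).
#' @slot anchor Numeric; empty for centered placement, else core-start
#'   offsets in bp relative to the window center.
#' @name InsertionLayout-class
#' @aliases InsertionLayout
#' @export
setClass("InsertionLayout",
  slots = c(sites = "list", orientations = "character",
            spacingBp = "integer", anchor = "numeric")
)

setValidity("InsertionLayout", function(object) {
  n <- length(object@sites)
  if (length(object@orientations) != n)
    return("orientations must match the number of sites")
  if (n && !all(object@orientations %in% c(">", "<")))
    return("orientations must be '>' or '<'")
  if (length(object@spacingBp) == 1L && object@spacingBp < 0L)
    return("spacing must be non-negative")
  if (length(object@anchor) && length(object@anchor) != n)
    return("anchor offsets must match the number of sites")
  TRUE
})

#' @param sites A [CTCFSiteSeq-class], or list of them; a single site is
#'   recycled to `n`.
#' @param orientations Character vector (or a single string like `"><"`).
#' @param spacingBp Core-to-core gap in bp (default 180).
#' @param n Number of copies when a single site is given.
#' @param anchor Optional explicit core-start offsets (bp, relative to the
#'   window center).
#' @return An `InsertionLayout`.
#' @rdname InsertionLayout-class
#' @export
insertionLayout <- function(sites, orientations = NULL, spacingBp = 180L,
                            n = NULL, anchor = numeric(0)) {
  if (is(sites, "CTCFSiteSeq")) sites <- list(sites)
  if (!is.null(orientations) && length(orientations) == 1L &&
      nchar(orientations[1L]) > 1L)
    orientations <- strsplit(orientations, "")[[1L]]
  if (!is.null(n) && length(sites) == 1L && n != 1L)
    sites <- rep(sites, n)
  if (is.null(orientations)) orientations <- rep(">", length(sites))
  if (length(sites) == 1L && length(orientations) > 1L)
    sites <- rep(sites, length(orientations))
  new("InsertionLayout", sites = sites, orientations = orientations,
      spacingBp = as.integer(spacingBp), anchor = anchor)
}

#' @rdname InsertionLayout-class
#' @export
emptyLayout <- function() insertionLayout(list(), orientations = character(0))

setMethod("show", "InsertionLayout", function(object) {
  n <- length(object@sites)
  cat("InsertionLayout:", n, "site(s), spacing", object@spacingBp, "bp,",
      if (length(object@anchor)) "fixed offsets" else "centered", "\n")
  if (n) cat("  orientation:", paste(object@orientations, collapse = ""), "\n")
})

#' Assemble an insertion layout into a background sequence
#'
#' Writes each core+flank unit over the background residues (replacement,
#' not lengthening, so the predictor window is preserved). Cores are placed
#' `spacingBp` apart (end-to-start) with the whole cassette centered at the
#' window midpoint, or at explicit anchor offsets. `"<"` units are
#' reverse-complemented as a unit before writing. Units overlapping each
#' other after flank extension, or running off the window, are an error.
#'
#' @param background Window-length character or `DNAString`.
#' @param layout An [InsertionLayout-class].
#' @return Character scalar of the same length as `background`.
#' @export
assembleInsertion <- function(background, layout) {
  bg <- .asSeqChar(background)
  n <- nchar(bg)
  k <- length(layout@sites)
  if (k == 0L) return(bg)
  coreLen <- 19L

  if (length(layout@anchor)) {
    coreStarts <- as.integer(round(n / 2 + layout@anchor))
  } else {
    span <- k * coreLen + (k - 1L) * layout@spacingBp
    first <- as.integer((n - span) %/% 2L + 1L)
    coreStarts <- first + (seq_len(k) - 1L) * (coreLen + layout@spacingBp)
  }

  chars <- strsplit(bg, "")[[1L]]
  written <- integer(0)
  for (i in seq_len(k)) {
    st <- layout@sites[[i]]
    unit <- siteSequence(st)
    coreOff <- nchar(st@flankUp) # 0-based offset of core within unit
    if (layout@orientations[i] == "<") {
      unit <- revComp(unit)
      coreOff <- nchar(st@flankDown)
    }
    uStart <- coreStarts[i] - coreOff
    uEnd <- uStart + nchar(unit) - 1L
    if (uStart < 1L || uEnd > n)
      stop("invalid layout: element ", i, " extends beyond the window")
    idx <- uStart:uEnd
    if (any(idx %in% written))
      stop("invalid layout: elements overlap after flank extension")
    written <- c(written, idx)
    chars[idx] <- strsplit(unit, "")[[1L]]
  }
  paste(chars, collapse = "")
}
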