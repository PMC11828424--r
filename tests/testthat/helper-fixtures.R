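# Shared fixtures. Everything is generated in code; expensive objects are
# memoised for the session.

.fx <- new.env(parent = emptyenv())

fgConsensus <- function() {
  if (is.null(.fx$cons)) .fx$cons <- motifConsensus(ctcfMotif())
  .fx$cons
}

# one-target surrogate at desk scale
fgTargets1 <- data.frame(name = "t", betaMult = 1, gammaMult = 1)

fgPred <- function(nBins = 64L, binSize = 512L, params = surrogateParams(),
                   oneTarget = TRUE) {
  surrogatePredictor(binSize = binSize, nBins = nBins, params = params,
                     targets = if (oneTarget) fgTargets1 else NULL)
}

fgCleanBg <- function(pred, seed = 42L) {
  key <- paste0("bg_", windowSize(pred), "_", pred@params$threshold, "_", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- cleanBackground(pred, seed = seed)
  .fx[[key]]
}

# mutate k random core positions
mutateCore <- function(core, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (p in sample(19L, k)) {
    cur <- substr(core, p, p)
    substr(core, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  core
}

# the canonical strong fixture site: consensus core, GC-rich flanks
fgStrongSite <- function(flankBp = 30L, id = "strong") {
  ctcfSite(fgConsensus(), strrep("G", flankBp), strrep("C", flankBp), id = id)
}

# random flank pair with a target GC level
fgRandomFlanks <- function(gc, flankBp = 30L, id = "flank") {
  draw <- function() paste(sample(c("G", "C", "A", "T"), flankBp, TRUE,
                                  prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
                           collapse = "")
  ctcfSite(fgConsensus(), draw(), draw(), id = id)
}

# independent brute-force insulation diamond mean
bruteInsulation <- function(V, w) {
  n <- nrow(V)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rows <- (i - w):(i - 1L); cols <- i:(i + w - 1L)
    if (min(rows) < 1L || max(cols) > n) next
    acc <- 0
    for (a in rows) for (b in cols) acc <- acc + V[a, b]
    out[i] <- acc / (w * w)
  }
  out
}

# flip a matrix through the anti-diagonal center (coordinate reversal)
flipMap <- function(M) M[nrow(M):1, ncol(M):1, drop = FALSE]

# a predictor stub with a fixed constant map, for contract-level tests
setClass("ConstantPredictor",
         representation(value = "numeric", nb = "integer", bs = "integer"),
         prototype(value = 0, nb = 16L, bs = 512L))
setMethod("predictContacts", "ConstantPredictor", function(object, seq, ...) {
  V <- matrix(object@value, object@nb, object@nb)
  list(t = ContactMap(V, binSize = object@bs,
                      clipRange = range(c(-2, 2, object@value))))
})
setMethod("nBins", "ConstantPredictor", function(x) x@nb)
setMethod("windowSize", "ConstantPredictor", function(object) object@nb * object@bs)
setMethod("targetNames", "ConstantPredictor", function(object) "t")
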