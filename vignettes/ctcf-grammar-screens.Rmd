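---
title: "Scoring CTCF grammar in predicted genome-folding maps"
author: "foldGrammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring CTCF grammar in predicted genome-folding maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldGrammar)
```

# Scope and model

`foldGrammar` quantifies how DNA sequence edits change predicted
genome-folding contact maps. The object of study is always a square matrix
of log observed/expected contact values at a fixed bin size (the
`ContactMap` class, default 2048 bp bins, values clipped to [-2, 2]), and
the edits are the field's standard in-silico perturbations:

* **disruption by permutation** — a span of the input window is replaced
  by a uniform random permutation of itself, which preserves nucleotide
  composition while destroying motif structure;
* **virtual insertion** — a 19-bp CTCF core motif, with genomic flanks,
  is written over the residues of a neutral background sequence
  (replacement, never lengthening, so the predictor's fixed window is
  preserved).

Both are scored by the square root of the sum of squared per-cell
differences between the maps predicted before and after the edit. A
mean-squared-difference variant exists as a method switch: the two
conventions circulate in the literature and we default to the square-root
form, which is the one stated alongside the score's definition and
matches prior use of "squared contact difference" scores. Scores are
collected in a `ScorePanel` indexed by subject × replicate axis
(permutations or backgrounds) × target × model, and reduced by averaging
in a declared order (replicates, then targets, then models). With mean
reduction the order is immaterial, but it is recorded because non-linear
reductions would not commute.

## Coordinates

Internally every coordinate is 1-based and closed, the R/Bioconductor
convention (IRanges, GRanges, `substr`). BED input and output are 0-based
half-open on disk; `rtracklayer` performs the conversion at the file
boundary. This keeps the package idiomatic for its ecosystem while keeping
BED as the interchange format.

## Contact-map storage

Maps are stored as plain tab-separated matrix text with a small comment
header (bin size, clip range, missing-bin indices). Plain text keeps the
fixtures and outputs transparent and diffable; the format round-trips
exactly through `writeContactMap`/`readContactMap`.

# The predictor contract and the surrogate

Everything downstream of prediction is predictor-agnostic: a predictor is
any object with a `predictContacts(object, seq)` method returning one
`ContactMap` per target, plus `windowSize`, `binSize`, `nBins`,
`targetNames`. Adapters for trained neural networks implement exactly this
surface; no network code ships in the package. Output-map cropping and
diagonal offsets are adapter concerns — the contract deliberately leaves
the map size a free parameter rather than fixing it to the input window.

The bundled `surrogatePredictor` is a mechanistic caricature of loop
extrusion, built so that every screen has a *known* ground truth:

1. `scanSites` scores every window of both strands against the bundled
   19-bp CTCF position probability matrix (log₂ odds vs uniform
   background), keeps hits at or above a threshold, and resolves overlaps
   greedily by score. Hits become barriers with an orientation and a
   strength in [0, 1].
2. Barrier strength couples a **core factor** (logistic in the log-odds
   score) with a **flank factor** (logistic in the GC fraction of the
   ±15 bp flanks). The flank factor gives flank-length sweeps and
   core×flank screens a non-trivial truth — GC-rich flanks strengthen a
   site — and makes the default strength exactly multiplicative in core
   and flank, so an all-pairs core×flank score matrix is exactly rank 1.
3. **Insulation**: the value of cell (i, j) is reduced by `beta` times the
   summed strength of barriers strictly between bins i and j, saturating
   at a floor.
4. **Dots**: every convergent pair (forward barrier upstream of a reverse
   barrier) adds a symmetric Gaussian bump of amplitude
   `gamma · s₁ · s₂ · exp(−d/d₀)` at the anchor pixel.
5. The map is clipped and smoothed with a small 2-D Gaussian.

The construction is deterministic and exactly strand-symmetric:
`predictContacts(revComp(s))` equals the coordinate-flipped prediction of
`s`, which the tests assert to floating tolerance. Shifting all motifs by
one bin shifts the (unsmoothed) map by one bin, and strengthening a
barrier never increases any cross-barrier contact before clipping.

## Surrogate parameters

All parameters live in `surrogateParams()` with documented defaults. They
are fixture parameters — chosen once so the surrogate behaves like a
plausible folding model at desk scale — not claims about biology:

* `threshold = 12` bits. The consensus core scores ~26 bits; random
  32-kb windows top out around 11–17 bits, so chance hits are rare and
  weak. Lowering the threshold towards 0 floods the map with spurious
  barriers.
* `logisticMid = 20`, `logisticScale = 2`: the strength midpoint sits well
  above the random-score tail, so chance hits have near-zero strength
  while one or two consensus mutations produce a graded strength ladder.
* `beta = 0.25`: a single strong site depletes straddling cells by ~0.2
  map units, so six stacked sites stay inside the clip range and dosage
  responses remain strictly monotone.
* `gamma = 2`, `d0 = 3e5` bp: dot amplitude exceeds the RMS of the
  surrounding insulated arms for strong sites, so bona fide convergent
  dots score positive under the 13×13 kernel.
* Three strength transforms: the default `"logistic"` (multiplicative
  core×flank), `"linear"` (strength strictly additive in per-position
  contributions — the ground truth for additivity of mutational effects),
  and `"saturating"` (a logistic of the additive raw value whose midpoint
  sits just above the reference site, so descending mutations traverse the
  convex part of the sigmoid and pairs of strong mutations saturate:
  observed double-mutant impacts are systematically *less* negative than
  the additive expectation).
* **Directional shading** (`shadeFrac`, off by default) spreads a fraction
  of each barrier's mass geometrically in its pointing direction. It is
  switched on only for the asymmetry experiments, where it reproduces the
  phenomenon that co-oriented cassettes shift the insulation minimum away
  from the cassette center, increasingly so for larger insulation windows;
  symmetric cassettes stay centered.

# Neutral backgrounds

`generateBackground` shuffles a genomic window in consecutive 8-bp chunks
(chunk order permuted uniformly; a final partial chunk travels as a unit)
and re-shuffles the current candidate until the target-averaged map signal
strength (sum of squared map values) drops below a threshold, rejecting
after 20 iterations. "Shuffling by 8-mers" is read as chunk permutation —
consistent with the 1/2/4/8/16/32-nucleotide chunk-size sweep that
motivates it — not as k-let-preserving Euler shuffling. The acceptance
threshold of 35 is quoted at the 640-bin reference map; because the
surrogate's fixtures run at reduced size, the effective threshold scales
as `(nBins/640)²` so that "flat" means the same per-cell amplitude at any
size. Whether the criterion applies per target or target-averaged is not
fixed by convention; we average over targets. For exactness-sensitive
tests the package also provides `cleanBackground`, which scrubs every
motif hit from a random sequence — a deterministic, fully featureless
background.

# Screens

* `flankSweep` extends genomic flanks symmetrically 0–35 bp around the
  core. Under the surrogate the curve rises while the flanks fill the
  15-bp GC window and is flat beyond — the known-truth analogue of
  flank-length saturation.
* `coreFlankScreen` scores all n² core×flank combinations and factorises
  the matrix by SVD. The rank-1 reconstruction `D¹·U¹⊗V¹` is reported with
  its Frobenius residual; signs are fixed so both leading vectors have
  non-negative mean. Cognate (genomic) pairs sit on the diagonal.
* `saturationMutagenesis`/`pairwiseMutagenesis` work on the canonical
  49-bp region (19-bp core ± 15-bp flanks). Pairwise impacts average the
  full 3×3 substitution enumeration (not a sample) and are compared with
  the additive expectation — the sum of averaged single-position scores.
* `grammarScreen` builds cassettes of n sites at a given core-to-core gap
  and orientation string. "Spacing" is implemented as the gap between one
  core's end and the next core's start (so a 180-bp gap accommodates two
  30-bp flanks); the alternative period reading differs only by 19 bp and
  the choice is recorded in the output. The spacing grid is a caller
  choice; sweeps across orientations {>>, <<, ><, <>} expose the
  convergent/divergent asymmetry.
* `dotBoundaryScenarios` probes feature specialisation with the two
  canonical layouts: divergent pair 180 bp apart scored globally
  (boundary strength) versus convergent pair far apart scored locally by
  the dot kernel at the expected anchor pixel. The default separation is
  400 kb; at reduced window sizes the tests use 60 kb, which the window
  check enforces.

# Map statistics

* `insulationProfile(map, w)`: mean of the off-diagonal w×w square
  connecting the w bins left of bin i with the w bins from i rightwards;
  undefined where the square does not fit. Window sizes 16/64/128 bins at
  2048 bp correspond to 32.8 kb/131 kb/262.1 kb diamonds.
* `insulationOffset`: signed bp distance of the profile minimum from the
  center bin (`floor(n/2)+1`), ties broken toward the center then
  leftward; a flat profile reports NA rather than 0.
* `dotScore`: 13×13 kernel, RMS(3×3 center) − RMS(arm cells). The arms
  are the four 3-bin-wide strips inside the footprint (5×3 up/down, 3×5
  left/right; opposing pairs total 10×3 — the stated arm geometry only
  fits a 13×13 footprint under this reading, which we adopt and document).
  RMS per region is the only reading under which a uniform patch scores
  exactly 0, which the tests assert.
* `callBoundaries`: local minima by prominence (plateaus report their
  leftmost bin); the prominence threshold default (0.1 map units) stands
  in for external "standard thresholds".
* `liThreshold`: Li's iterative minimum cross-entropy threshold, computed
  on scores shifted to a positive scale by a range-proportional offset so
  the threshold is scale- and shift-equivariant. `classifySensitivity`
  then labels a boundary sensitive when the maximum tiled disruption
  score within ±28 kb (±14 tiles of 2048 bp) reaches the threshold.
* `orientationHistogram`: the highest-scoring tile per boundary is
  overlapped with stranded motif sites; all-`+` tiles are right-oriented,
  all-`-` left, anything else "other". The total count profile is
  smoothed by a cubic smoothing spline followed by a Gaussian kernel
  (σ in tiles, configurable).

# Fixtures and problem sizes

`synthGenome` and `synthMap` generate every test input in code: random
background with planted cores (orientation, flank GC level, truth table)
and symmetric maps with planted straddle-depletion boundaries, Gaussian
dots and optional symmetric noise. Both are pure functions of
specification and seed.

The test suite and the acceptance script run the surrogate at 48–128 bins
with 512–2048 bp bins (32 kb–262 kb windows) and the insulation-recovery
maps at 320 bins; the full 640-bin geometry is exercised by the default
constructor. These sizes were chosen so the complete suite runs in a few
minutes on one CPU while every screen retains its qualitative structure.

# What passing tests do and do not show

The surrogate shares the *structure* of a trained sequence-to-contact-map
model — motif-driven, strand-symmetric, insulation- and dot-forming — but
none of its learned nuance: no repeat effects, no cell-type-specific
differences beyond amplitude scaling, no distance-decay or coverage noise
(map noise in fixtures is additive Gaussian only). Quantities that
intrinsically require trained weights and genome-scale data — held-out
prediction accuracy, the printed insertion-versus-disruption correlation
of real site panels, the ~15-bp flank saturation length on genomic
flanks, the ~70 kb/~600 kb orientation maxima, the fraction of
disruption-sensitive boundaries — are therefore *not* reproduced as
numbers; the suite asserts instead that the machinery recovers planted
truth exactly and mirrors each qualitative phenomenon under the
surrogate. The acceptance script reports the package's own computed
quantities under the fixed study conditions.

# Known limitations

* The surrogate's dot amplitude is a free parameter; weak convergent
  pairs can legitimately score negative under the dot kernel because
  their insulated arms outweigh the focal bump.
* Fold partitioning balances by total region bp with a largest-first
  greedy rule (ties to the lowest fold index); the upstream alignment
  criterion (>500 kb) is the caller's responsibility.
* `kmerEnrichment` uses a pooled label-permutation null ("bootstrap" in
  the loose sense common for group-difference tests); a
  resample-with-replacement variant is not currently exposed.
* Orientation histograms require stranded sites; strandless input is an
  error, not a silent "other".
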