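Package: foldGrammar
Title: In Silico Perturbation Screens for CTCF-Driven Genome Folding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores how DNA sequence edits (span permutation, virtual motif
    insertion, saturation and pairwise mutagenesis, multi-site cassettes)
    change predicted genome-folding contact maps, together with the
    downstream map statistics (insulation profiles and offsets, dot and
    boundary scores, sensitivity classification) and motif statistics
    (logos, weighted Jensen-Shannon difference, k-mer enrichment, partial
    correlations). The sequence-to-contact-map predictor is a pluggable
    contract; a mechanistic loop-extrusion surrogate predictor is bundled so
    every procedure runs at desk scale without trained network weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'foldGrammar-package.R'
    'AllGenerics.R'
    'ContactMap-class.R'
    'ScorePanel-class.R'
    'backgrounds.R'
    'folds.R'
    'io.R'
    'layout.R'
    'map-features.R'
    'motif-stats.R'
    'perturb.R'
    'pfm.R'
    'predictor.R'
    'screens.R'
    'synthetic.R'
    'utils.R'
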