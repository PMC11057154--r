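Package: utrscape
Title: Regulatory Architecture of 5' Untranslated Regions Across Gene Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates and classifies upstream translation-initiation elements
    (uORFs, overlapping ORFs, N-terminal extensions and start-stops) in 5'
    untranslated regions, scores their Kozak context, translational efficiency
    and codon optimality, and assembles per-gene regulatory feature vectors.
    Provides a dinucleotide-composition-preserving Eulerian-walk shuffle with an
    observed/expected codon depletion statistic, classification of 5'UTR variant
    effects on the upstream ORF landscape (uAUG-gained, uAUG-lost, uSTOP-lost,
    uSTOP-gained) including saturation enumeration of small variants, and a
    cohort statistics layer that stratifies genes by loss-of-function constraint
    (LOEUF) deciles, disease gene sets, transcription start site diversity and
    expression, with Bonferroni control over an explicit test ledger. A
    synthetic cohort generator emulates the study conditions at toy scale so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
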