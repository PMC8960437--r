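Package: orthopeak
Title: Cross-Species Conservation Analysis of Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies transcription factor ChIP-seq binding sites and their
    target genes as conserved, alternative, or species-specific between two
    species, and quantifies the association of those classes with expression
    divergence, DNA motif content, and transposable element overlap. Builds
    per-species consensus peak sets from replicate narrowPeak calls, maps
    intervals between genomes through UCSC chain files with single-spanning-
    range liftOver semantics, scans position weight matrices with exact
    p-values, and tests transposable element enrichment with chi-square and
    label-permutation statistics. Includes a fully specified two-species
    synthetic data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
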