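Package: RepeatSpan
Title: Spanning-Read Genotyping and Interruption-Motif Decomposition of
    Tandem Repeat Expansions from Noisy Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterizes large tandem repeat expansions (such as the
    GGCCTG hexanucleotide expansion in intron 1 of NOP56 that causes
    spinocerebellar ataxia type 36) from noisy single-molecule long reads.
    Provides a ground-truthed simulator of CLR-like reads over an expanded,
    interrupted repeat locus; construction of the native/expanded ("fake")
    reference pair used for alignment-based spanning-read discovery;
    flank-anchor semi-global alignment to classify reads as fully or
    partially spanning the repeat tract and to extract the tract;
    dynamic-programming tokenization of tracts into core and interruption
    motifs; per-sample repeat-number summaries against the pathogenic
    threshold; motif nucleotide-ratio tables; and waterfall schematics of
    per-read motif structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
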