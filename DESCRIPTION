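Package: tescape
Title: Transposable-Element Annotation Curation, Repeat Landscapes and
    Windowed Genome-Feature Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes RepeatMasker-style transposable-element (TE)
    annotations into a curated set of TE copies: parses hit (".out") and
    alignment (".align") tables, merges hit fragments into copies, assembles
    LTR retrotransposon structures, applies the 80-80-80 retention rule, and
    computes per-copy CpG-adjusted Kimura 2-parameter divergence with
    conversion to insertion age and a recent/ancient age classification.
    Builds divergence-binned repeat landscapes, tiles the genome into
    fixed-width windows carrying TE coverage (overall, per type, per age
    class), gene coverage, GC content, CpG-island coverage and
    distance-weighted recombination rate, and provides the statistical
    battery used to relate them: Kendall's tau-b, partial Kendall rank
    correlation with Bonferroni correction, Kruskal-Wallis comparisons of
    macro- and microchromosomes, relative per-chromosome coverage and
    coverage-versus-length regression. A synthetic-genome simulator plants
    TE copies at known divergence, with fragmentation and nesting, and emits
    every input format the pipeline reads, so the whole analysis is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    readr,
    stringr,
    tibble,
    tidyr,
    generics,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
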