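Package: asorf
Title: Existence, Emergence and Loss of Antisense Overlapping Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic models for the existence, mutational gain and loss of
    open reading frames (ORFs) that overlap protein-coding genes in antisense
    orientation, in each of the three possible reading frames and under three
    levels of purifying selection on the sense gene. Provides composition models
    (GC-content based or empirical oligomer frequency tables), exhaustive
    dicodon enumeration for frame-specific stop-codon probabilities, stop/start
    gain, loss and stay event probabilities from a six-class mutation-bias
    spectrum, expected ORF counts over annotated overlap and intergenic regions,
    a getorf-style ORF scanner with antisense frame classification, the
    comparison statistics used on scan outputs, and a synthetic genome generator
    with forward mutation simulation for model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
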