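Package: ripITS
Title: Detection and Population Analysis of RIP-Mutated ITS Pseudogenes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying repeat-induced point mutation (RIP) in the
    ribosomal internal transcribed spacer (ITS) region of fungal populations.
    Provides a population simulator that plants RIP-mutated ITS paralogs
    (context-biased G:C to A:T transitions) alongside functional copies,
    pseudogene detection by mutation-spectrum comparison against functional
    counterparts, RIPCAL-style dinucleotide context classification, haplotype
    collapsing of identical sequences, GC-content and p-distance summaries
    with pairwise deletion, neighbor-joining trees with monophyly tests, and
    an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
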