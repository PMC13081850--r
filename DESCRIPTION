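Package: oligopool
Title: Declarative Design of DNA Oligonucleotide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Build complex oligonucleotide pool designs (deep mutational
    scanning libraries, MPRA libraries, in silico perturbation libraries)
    as directed acyclic graphs of composable operations. Libraries are
    lazily evaluated: every sequence is indexed by a non-negative integer
    state that is decomposed across the graph by exact mixed-radix
    arithmetic, so pool sizes are available without generating a single
    sequence, and each sequence, its automatically assigned name, and its
    design card are pure functions of the state and a master seed.
    Includes region-tagged sequences with XML-style markup, codon-aware
    mutagenesis, motif and barcode operations, ANSI-styled terminal
    rendering, declarative design files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
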