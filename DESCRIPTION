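Package: coihap
Title: In Silico PCR-RFLP Typing and Haplotype Population Genetics for
    Insect COI Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for molecular surveys of insect populations typed at the
    mitochondrial cytochrome oxidase subunit 1 (COI) locus, motivated by
    Bemisia tabaci cryptic-species monitoring. Provides in-silico PCR-RFLP
    typing of COI amplicons (IUPAC-aware primer search, amplicon extraction,
    restriction digestion with ApoI or any user-defined enzyme, and
    fragment-pattern classification against a diagnostic library including
    the MED Q1, Sardinian Q1 and Q2 haplogroup patterns), population-genetics
    statistics computed from first principles (haplotype collapsing, Nei's
    haplotype diversity, nucleotide diversity, Tajima's D and Fu's Fs via the
    Ewens sampling formula), median-joining haplotype networks, TN93
    distances with neighbor-joining summaries, a synthetic COI population
    generator for validation, and a pipeline driver that produces
    survey-style composition reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
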