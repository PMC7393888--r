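Package: plastmut
Title: Directions, Spectra and Rates of Mutations in Plastome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls nucleotide and structural mutation events from a
    whole-plastome multiple sequence alignment of a small clade, polarizes
    each event against hierarchical outgroups on a fixed dated phylogeny,
    classifies events into substitution classes, indels, tandem repeats,
    microsatellites and stem-loop inversions, quantifies the association
    between structural and nucleotide mutations, and estimates per-site
    mutation rates. Includes a plastome evolution simulator that evolves an
    annotated genome along the dated topology under parameterized
    substitution and structural-mutation processes and emits the true
    alignment together with a complete event log, so every analysis stage
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
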