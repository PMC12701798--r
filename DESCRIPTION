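Package: oncosim
Title: Agent-Based Simulation of Tumor Evolution, Metastasis, and DNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tumor growth, somatic mutation under genotype-driven
    selection, and metastatic cell migration across anatomical sites using a
    clone-level agent-based branching process over discrete generations.
    Genomes are represented as region-resolved chromosome strands carrying
    SNVs, mutated by five mechanisms (SNV, segmental gain/loss, chromosome-arm
    and whole-chromosome missegregation, whole-genome duplication) under
    multiplicative, site-specific fitness landscapes with logistic population
    growth. After forward simulation, sampled cells are resolved to a binary
    single-cell lineage via a coalescent over recorded clone sizes, passenger
    mutations are added top-down, and the package emits ground-truth clone and
    cell lineage trees, migration graphs, allele-specific copy-number and SNV
    profiles, single-cell or bulk read counts, and mutated reference sequences
    for downstream short-read simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml,
    Matrix,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
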