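Package: cysmotif
Title: Conserved-Cysteine Scaffold Classification and Motif-Pattern
    Fingerprinting of Insect Chemosensory Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies candidate insect nonreceptor olfactory proteins
    (odorant-binding proteins, chemosensory proteins and sensory neuron
    membrane proteins) from transcript or protein FASTA input. Extracts
    open reading frames by six-frame translation, matches
    spacing-constrained conserved-cysteine scaffold patterns to call OBP
    subclasses (classic, minus-C, plus-C) and CSPs, screens for the
    two-transmembrane SNMP topology with a Kyte-Doolittle hydropathy
    window, discovers ungapped sequence motifs de novo by ZOOPS
    expectation-maximization with empirical shuffle-null significance,
    condenses per-sequence motif occurrences into ordered motif-pattern
    fingerprints, and annotates those patterns onto phylogenetic trees
    (iTOL colorstrip output plus clade-homogeneity summaries). A seeded
    synthetic-data generator emits labelled protein families and
    transcripts with planted scaffolds, motifs and transmembrane
    stretches so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Matrix,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
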