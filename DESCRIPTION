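Package: chsevol
Title: Identification, Classification and Horizontal-Transfer Analysis of
    Chitin Synthases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of chitin synthases (CHS) and
    related family-2 glycosyltransferases: a gene-family evolution simulator
    (duplication, loss, horizontal transfer with compositional signal,
    chimeric fusions, co-transferred gene neighbourhoods), catalytic-motif and
    PSSM screening of candidate proteins, alignment-column trimming,
    neighbor-joining trees with nonparametric bootstrap, monophyly-based
    classification, horizontal-gene-transfer detection from phylogenetic
    incongruence, G+C composition and synteny, and chimeric-protein diagnosis
    by split-alignment phylogenetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
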