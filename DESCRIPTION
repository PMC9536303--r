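Package: mirsignet
Title: Neoplasm-Specific Signature Modules of miRNA Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives neoplasm-specific miRNA-interaction signature modules from
    curated miRNA-disease association tables, consensus miRNA target
    predictions, and Gene Ontology annotation. Harmonizes association exports
    from heterogeneous database dialects, computes information-content based
    term, gene and miRNA functional similarity (Lin/Resnik with best-match
    average aggregation, plus an asymmetric significance-weighted set measure),
    builds one weighted miRNA similarity network per neoplasm group, prunes
    each network to its top weight decile, and extracts maximal-clique modules
    that are mutually exclusive across the network collection, with
    degree-preserving permutation significance and false-discovery-rate
    control. Includes a fully seeded synthetic-data generator (layered GO-like
    ontologies, per-tool target predictions with a planted consensus core, and
    association worlds with planted group-exclusive modules) so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
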