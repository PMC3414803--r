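Package: famintr
Title: Family Inference and Mobile-Element Annotation for Tyrosine
    Recombinases
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Clusters tyrosine-based site-specific recombinase (TBSSR)
    proteins into families from all-vs-all Smith-Waterman similarities
    using Markov clustering (MCL), with the inflation factor selected by
    the intra-cluster clustering coefficient (ICCC).  Each family is
    aligned, scanned for the catalytic R...Y motif, and annotated with its
    mobile-genetic-element (MGE) type composition and specificity.
    Composite recombinase elements (RIT trios, Tn554-like tandems, BIM
    pairs) are detected on annotated replicons by explicit gene-context
    rules, and host sharing of families is summarised as a weighted
    host-host network.  A synthetic-corpus generator with planted ground
    truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
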