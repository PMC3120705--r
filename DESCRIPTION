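Package: otupipe
Title: Amplicon Read Filtering, OTU Clustering and Taxonomic Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable pipeline for processing tagged amplicon reads
    (for example 454-style fungal ITS libraries) into operational taxonomic
    units. Provides quality filtering and trimming of multiplexed reads
    (tag and primer matching by Needleman-Wunsch alignment with a mismatch
    allowance, incompatible end-tag screening, ambiguity and length filters,
    homopolymer collapsing, adaptor removal and dereplication with abundance
    tracking), de novo OTU construction by single-linkage or greedy
    incremental clustering at identity and coverage thresholds, parsing and
    summarisation of BLAST tabular output including removal of uninformative
    environmental hits, OTU-by-sample abundance matrices, and a synthetic
    read simulator with full ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
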