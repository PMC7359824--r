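Package: barcurate
Title: Iterative Curation of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating DNA barcode reference libraries by the
    iterative combination of multi-method species delimitation and
    multi-method specimen assignment. Computes Kimura two-parameter (K2P)
    pairwise distances with pairwise site deletion and barcode-gap
    statistics; delimits operational taxonomic units (OTUs) with four
    algorithms (a refined single-linkage approximation, automatic
    barcode-gap discovery, Poisson tree processes in single- and
    multi-rate flavours, and the general mixed Yule-coalescent model) and
    builds a co-membership consensus partition; assigns query sequences to
    reference OTUs with back-propagation neural networks, fuzzy-set
    nearest-neighbour membership, and an alignment-free k-mer variant,
    with consensus verdicts and a selected-OTU/nearest-neighbour ratio
    diagnostic for false positives; and orchestrates the two-round
    workflow in which newly delimited OTUs are promoted into the library.
    A fully seeded synthetic barcode-library generator with known OTU
    truth (cryptic lineages, unsampled query OTUs, mislabeling) makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
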