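Package: taxsift
Title: Hybrid Taxonomic Classification by Containment Screening and
    Coverage-Weighted Lowest Common Ancestor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-stage hybrid classifier for metagenomic contigs and
    reads. Reference genomes are screened with bottom-s MinHash sketches
    and a containment index, candidate references are chosen with a
    sample-adaptive threshold that lowers in fixed steps to a floor,
    alignments (PAF) are reduced to per-query coverage, and each query is
    assigned a consensus lineage by a coverage-weighted lowest-common-
    ancestor classifier whose confidence is the product of per-rank
    consensus fractions. Includes NCBI-style taxonomy handling, CAMI-style
    profile metrics (presence precision/recall/F1, L1 total variation,
    Bray-Curtis, Pearson, contig accuracy), and a seeded synthetic
    community generator (fragmentation, read windowing, point mutation
    with short indels, reference ablation) so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
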