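Package: toledna
Title: Tree-of-Life eDNA Metabarcoding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-assay ('tree of life') environmental DNA
    metabarcoding surveys: exact-match demultiplexing of fusion-tag amplicon
    reads and per-sample quality control, score-filtered lowest-common-ancestor
    (LCA) taxonomic assignment with a conservative species rule and
    negative-control subtraction, multi-assay biodiversity aggregation with
    analytic (hypergeometric) rarefaction and depth normalisation, and a
    haplotype-diversity workflow covering amplicon error-rate calibration from
    single-source libraries, frequency and replicate filtering, greedy OTU
    clustering, gap-aware distance recoding and minimum spanning haplotype
    networks. Includes a synthetic-data generator (taxonomies, reference
    barcodes, assay panels, community and single-source read sets, oracle hit
    tables) so the whole pipeline runs and is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
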