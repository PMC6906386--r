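Package: dietmir
Title: Cross-Kingdom Small RNA Provenance, Plant miRNA Annotation and
    Target Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for dietary (cross-kingdom) small RNA
    studies in sap-feeding insects. Partitions small RNA reads among
    candidate source genomes (host insect, obligate symbiont, host
    plant, bacteria, viruses) under a less-than-two-mismatches rule;
    post-processes plant miRNA precursor calls (duplicate collapse,
    mature/star designation, known/novel classification by tiered
    homology evidence); detects plant miRNAs in insect read sets by
    perfect-match counting; profiles reads over precursor regions
    (mature, star, loop, ends, fragments); intersects multi-tool
    miRNA target predictions in the seed region; and tests COG
    functional enrichment of target sets against a Monte Carlo
    resampling null with one-to-many isoform expansion and empirical
    two-tailed p-values. Includes a synthetic-data generator so the
    whole pipeline runs and is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
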