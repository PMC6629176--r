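Package: secirc
Title: Discovery of Super-Enhancer-Associated Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for nominating super-enhancer-associated
    circular RNAs (SE-circRNAs) from H3K27ac enhancer catalogs and circRNA
    expression profiles. Calls super-enhancers from stitched enhancer peaks
    with a rank-curve tangent cutoff, assigns enhancers to the most proximal
    circRNA promoters, scores tissue and developmental-stage specificity with
    a Jensen-Shannon index, filters candidates by cross-species conservation
    and fold change between developmental stages, and scans circularized
    sequences for miRNA seed sites (back-splice-junction aware) and
    transcription-factor motifs. Ships a synthetic-data generator with a
    planted ground-truth ledger so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
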