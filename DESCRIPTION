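Package: telotide
Title: Telomere Length Estimation from Capture-Enriched Nanopore Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Isolates telomere-containing nanopore reads, classifies strand
    of origin, locates the enrichment capture probe with bounded-error
    matching, detects the subtelomere-to-telomere boundary with a
    dual-threshold jumping-window algorithm over telomere+1N repeat
    content, applies per-read quality filters, and reports per-read
    telomere lengths. Includes a synthetic long-read simulator with
    ground truth so the full pipeline can be exercised and validated
    offline, plus barcode demultiplexing for multiplexed runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
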