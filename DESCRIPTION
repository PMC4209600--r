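Package: mirEscape
Title: Seed-Site Scanning and 3'UTR-Shortening Analysis of miRNA Target Escape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking why predicted microRNA targets escape repression
    in an over-expression screen. Derives canonical 8mer/7mer-m8/7mer-A1 seed
    motifs from a mature miRNA and scans 3'UTR sequences for target sites;
    quantifies expression as RPKM and classifies genes as repressed, increased,
    unchanged or low-read-excluded from two-condition count data; detects 3'UTR
    shortening from per-base coverage with a two-segment changepoint fit and a
    distal-usage-index ratio, and decides whether a seed site is lost to the
    shortening; scores isoform-level seed escape; and runs hypergeometric
    over-representation of up-, down- and seed-containing gene lists against
    GMT collections. A truth-annotated synthetic-data generator emulates the
    full screen (UTR FASTA, BED12 models, negative-binomial counts, bedGraph
    coverage, GMT) so every stage is testable end to end, and a deterministic
    preset reproduces the cohort structure of a published miR-155/MCF-7 screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
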