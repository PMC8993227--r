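Package: patapa
Title: Poly(A) Tag Sequencing Analysis of Alternative Polyadenylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for alternative polyadenylation (APA) analysis
    from 3' end poly(A) tag sequencing (PAT-seq) data. Reads aligned poly(A)
    tags (SAM/BAM/BED), removes internal-priming artifacts using the genomic
    A-content downstream of each putative cleavage site, clusters tags into
    poly(A) clusters (PACs), assigns PACs to genes and genomic regions with
    a 3' UTR extension rescue, tests PACs and genes for differential
    expression between two conditions with a moderated negative-binomial
    test, quantifies usage-weighted 3' UTR length dynamics (lengthening and
    shortening) with a condition-correlation direction statistic and
    chi-square usage-shift tests, and calls APA switching,
    condition-specific, and condition-inducible events. Includes a seeded
    synthetic-data generator with planted APA dynamics that provides ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    stringi,
    ggplot2,
    generics,
    withr,
    stats,
    tools,
    utils,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
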