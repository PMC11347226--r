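Package: screentriage
Title: Pooled shRNA Dropout Screen Analysis and Candidate Target Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for triaging candidate cancer dependencies
    from pooled shRNA dropout screens run in parallel tumour-cell,
    allograft and fibroblast contexts. Implements exact-match guide
    counting with library-representation QC, negative-binomial
    differential-abundance testing with median-of-ratios normalization,
    gene-level median-of-guides aggregation with non-targeting pseudo-gene
    nulls, dependency-reference essentiality scoring, gene-set activity
    scoring with co-expression, overexpression and survival filters, and
    spike-in-normalized promoter occupancy analyses. A synthetic-data
    generator reproduces the statistical structure of each input so the
    full pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    rlang,
    Biostrings,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
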