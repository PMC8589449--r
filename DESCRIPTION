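Package: scanseq
Title: TSS-Seq Promoter-Window Metrics and a Promoter-Scanning Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of transcription start site sequencing
    (TSS-seq) in organisms that initiate transcription by promoter scanning.
    Builds strand-oriented promoter-window count tables from stranded
    bedGraph or BED 5'-end data, computes per-promoter TSS distribution
    statistics (expression, percentile positions, median, spread) and
    mutant-versus-wild-type shift and spread-change tables with their
    significance tests, performs replicate correlation QC, hierarchical
    clustering and PCA of shift profiles, and quantifies primer-extension
    lanes in user-defined TSS bins. A stochastic "shooting gallery"
    promoter-scanning simulator with known initiation-efficiency and
    scanning-processivity parameters generates synthetic libraries, with
    closed-form expected distributions, so the whole pipeline is verifiable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
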