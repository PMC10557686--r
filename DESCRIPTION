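Package: fiberhap
Title: Haplotype-Resolved Single-Molecule Chromatin Fiber Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of haplotype-phased single-molecule chromatin
    architecture (Fiber-seq) data. Aggregates per-molecule FIRE
    (Fiber-seq Inferred Regulatory Element) precision scores into a
    phred-scaled accessibility signal and calls peaks under a
    genome-wide Bonferroni threshold; tests every peak for
    haplotype-specific accessibility with Fisher's exact test and
    Benjamini-Hochberg correction; scores single-molecule co-dependency
    between regulatory element pairs; detects regional allelic
    imbalance such as X-chromosome-inactivation spreading with a
    Mann-Whitney U test and estimates the silenced-cell fraction;
    compares haplotype-resolved CpG methylation; and tests
    allele-specific expression from phased full-length transcripts.
    Ships a synthetic chromatin-fiber generator so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
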