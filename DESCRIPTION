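Package: txclass
Title: Reference-Guided Transcript and Exon Classification with
    Replicate-Supported Novel Transcript Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of assembled RNA-Seq transcript models
    ("transfrags") against reference annotation: five-way exon classification
    (Exact, Overlap, Within, Novel-T, Novel-U) behind an empirical read-count
    significance threshold (Tukey-fence outlier removal plus a lower-tail
    quantile minimum), intron-chain based transcript classification into
    complete, partial and novel matches, replicate-supported discovery of
    intergenic novel transcripts with treatment partitioning and
    differential-expression intersection, and cross-platform (RNA-Seq versus
    microarray) statistics: RPM and log2 quantile normalization, median-polish
    probe summarization, signed fold changes, permutation t-test DEG calling,
    and quartile-stratified Spearman correlation. Includes a deterministic
    synthetic-data generator with planted ground truth and a reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    limma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
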