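Package: methpanel
Title: Differential Methylation Testing and Biomarker Panel Validation for
    Targeted Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for targeted bisulfite
    sequencing studies of DNA methylation biomarkers: ingestion of
    Bismark-style per-cytosine reports, coverage filtering, per-CpG
    differential methylation testing in a paired design using
    empirical-Bayes moderated t-statistics on the two-level
    (methylated/unmethylated) count structure, per-region Simes
    aggregation with Benjamini-Hochberg correction, rule-based calling of
    differentially methylated regions, top-k marker panel selection, and
    panel-based tumor versus normal-mucosa classification with ROC/AUC
    validation. Includes a synthetic cohort generator that emulates a
    paired, batched study design with ground-truth region classes, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
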