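Package: cnvbench
Title: Benchmarking Copy-Number-Variant Call Sets Against Reference Truth Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for copy-number-variant (CNV) detection from
    SNP-array data. Matches caller output against reference truth sets under a
    combined-span (union) overlap criterion with optional deletion/duplication
    state consistency, stratifies recovery rates by probe support and by CNV
    population frequency, measures concordance between gold-standard call
    sets, classifies singleton and program-specific calls across callers,
    scores calls against qPCR-derived copy numbers (delta-delta-Ct
    quantification, positive predictive value, false-positive and
    false-negative rates), and scans for genotyping plate effects with an
    exact 2x2 test. A synthetic-data module generates truth sets, probe
    manifests, multi-caller call sets, plate structures, and qPCR tables so
    the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
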