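Package: aarscan
Title: Pan-Cancer Multi-Omics Profiling and Ranking of Aminoacyl-tRNA
    Synthetase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for assessing aminoacyl-tRNA synthetase
    (aaRS) and AIMP genes across cancer cohorts at three molecular levels:
    genomic alteration profiles built from thresholded copy-number calls
    and mutation tables, tumor-versus-normal differential expression with
    a fold-change plus FDR decision rule, and expression-stratified
    Kaplan-Meier survival maps with median splits, log-rank tests and
    Mantel-Haenszel hazard ratios. Per-gene DNA, mRNA and survival scores
    are min-max normalized and averaged into a composite that ranks genes
    from most cancer-inhibiting to most cancer-promoting. A seeded
    synthetic cohort generator with planted oncogene-like and
    suppressor-like archetypes makes every stage testable without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    survival,
    stats,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
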