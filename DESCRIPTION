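Package: countbench
Title: Benchmarking Count-Based Differential Expression Tests on Simulated RNA-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained benchmarking toolkit for count-based RNA-seq
    differential expression analysis. Simulates replicated two-group RNA-seq
    experiments from a negative binomial model with gamma-distributed fold
    changes under seven preset scenario designs, provides reference
    implementations of six families of count-based differential expression
    tests (Poisson MA-style, negative binomial exact with empirical-Bayes
    dispersion shrinkage, trended-dispersion pooled NB, power-law-dispersion
    NB, two-stage Poisson, and an empirical-Bayes NB posterior method), and
    evaluates them with truth-aware metrics (significant-gene counts, false
    and true positive rates at Benjamini-Hochberg FDR cutoffs, AUC-ROC) and
    truth-free concordance metrics (Spearman correlation, intraclass
    correlation, overlap and singleton analysis, identification frequency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
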