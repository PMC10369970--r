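Package: chromscore
Title: Regulatory Activity Scoring and Genome Annotation from Chromatin Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains per-dataset "expert" ensembles of weighted L2-penalized
    logistic regressions that predict activating regulatory activity from
    binned chromatin-mark features, scores the genome at 25 bp resolution,
    combines experts into a mean ChromScore track with quantile
    normalization, and segments the genome into ChromScoreHMM states with a
    multivariate Bernoulli-emission hidden Markov model learned by
    Baum-Welch. Includes harmonized labeling rules for MPRA, STARR-seq,
    HiDRA and CRISPRi readouts, overlap/TSS/expression/repeat enrichment
    analyses, and a seeded synthetic-epigenome generator with planted
    regulatory elements so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
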