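Package: riboflux
Title: Biophysical and Machine-Learning Prediction of Protein Expression
    from mRNA Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-gene protein expression in E. coli-style bacteria
    from sequence alone. Combines a biophysical translation-rate engine
    (Shine-Dalgarno initiation-rate energetics, per-codon elongation rates,
    and a stochastic TASEP ribosome-traffic simulation) with an
    eleven-feature mRNA/protein feature extractor, a learned translation-rate
    stage ("New_TR") offering six regressor families, and an exhaustive
    feature-combination search scored by Spearman rank correlation. Ships a
    synthetic operon/expression generator so the whole pipeline is testable
    without external data downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stringr,
    limma,
    seqinr,
    glmnet,
    ranger,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
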