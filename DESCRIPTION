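Package: sldsf
Title: Unsupervised Cancer Characteristic Gene Selection by Deep Sparse Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Selects cancer characteristic genes from gene-expression matrices
    without class labels by sample learning based on deep sparse filtering
    (SLDSF). Each layer learns a sparse filter matrix by minimizing the L1
    norm of a row- then column-L2-normalized, soft-absolute-activated sample
    distribution with L-BFGS; layers are stacked greedily with inter-layer L2
    normalization, and genes are ranked by the column sums of the final sample
    distribution (the evaluating vector). Includes delimited-text matrix I/O
    with orientation handling, per-sample standardization, a seeded synthetic
    data generator with planted differentially expressed genes, recovery
    metrics, and a command-line interface.
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
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
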