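Package: g3cs
Title: Gene-Correlation-Guided Unsupervised Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised selection of informative genes from expression
    matrices by a regularized regression / orthogonal matrix-factorization
    model. A row-sparse projection maps genes onto a small set of pseudo
    cluster labels; a gene-pair covariance penalty discourages selecting
    mutually redundant genes and a k-nearest-neighbour graph Laplacian over
    samples preserves local sample geometry. The model is fitted by
    alternating closed-form, Procrustes and multiplicative KKT updates.
    Includes a synthetic-data generator with planted informative, redundant
    and noise genes, and a cross-validated classification harness for
    evaluating selected gene subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    e1071,
    randomForest,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
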