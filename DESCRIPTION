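Package: fragCDR
Title: Subcomponent-Guided, Interpretable Cancer Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts log-IC50 drug responses of cancer cell lines from
    pairwise interactions between drug subcomponents (BRICS molecular
    fragments embedded as circular fingerprints and encoded with a gated
    recurrent unit) and cell-line subcomponents (Cancer Gene Census gene
    subsets, tumour-type masked and encoded with a one-dimensional
    convolution). All fragment-by-subset pairs are scored with a trainable
    bilinear form into an interaction map, which is lifted to a weighted
    complete bipartite graph, propagated with graph convolutions, pooled,
    and decoded together with masked matrix-factorization side information
    into the predicted response. The interaction map doubles as the model's
    interpretability surface: softmax heatmaps, top interaction extraction,
    and ranking of unmeasured drug-cell line combinations. Includes
    warm-start and cold-start cross-validation utilities and a fully
    synthetic data generator so the package builds and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
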