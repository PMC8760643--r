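Package: dyndlt
Title: Dictionary-Learning Pseudotime Estimation for Dynamic Transcriptomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free pseudotime estimation and marker-gene (gene-module)
    detection from dynamic transcriptomic count data via thin, positive,
    unit-norm dictionary learning with dense orthogonal-matching-pursuit
    coefficients (dynDLT). Includes a simulation benchmark that injects
    dynamic expression patterns into negative-binomial count baselines,
    uniform adapters for ICA, NMF, PCA, t-SNE and UMAP comparisons, a
    minimum-spanning-tree polygonal-reconstruction pseudotime mode, and a
    Spearman-correlation / marker-overlap evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    Rtsne,
    uwot,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
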