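Package: dualCCA
Title: Regularized Dual Canonical Correlation Analysis for Paired Omics Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates two high-dimensional paired omics matrices (for example
    log2 gene-expression values and log2 copy-number ratios measured on the same
    samples) by ridge-regularized canonical correlation analysis solved in its
    dual (Gram-matrix) formulation, so that computation scales with the number of
    samples rather than the number of variables. Also provides the PCA+CCA
    variant (dual principal component analysis of each set followed by classical
    CCA on the component scores), cross-validated selection of the two ridge
    parameters on a grid, a permutation null for the cross-validated canonical
    correlation, and interpretation tools: cross-loadings, top-k relevance lists,
    redundancy coefficients, genome-ordered relevance tables and superimposed
    standardized sample coordinates. A synthetic-data generator with closed-form
    population canonical correlations supports validation and examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
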