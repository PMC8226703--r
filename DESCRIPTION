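Package: afpdomains
Title: Antifreeze Protein Identification from Functional Domain Composition
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies antifreeze proteins (AFPs) from their InterPro
    functional-domain composition. Proteins are encoded as sparse binary
    protein-by-domain incidence matrices, domains are ranked by the
    minimum-redundancy-maximum-relevance (mRMR) criterion using discrete
    plug-in mutual information, and nested top-k feature subsets are
    evaluated by incremental feature selection (IFS) with a random-forest
    classifier under stratified 10-fold cross-validation. The optimum
    feature subset and classifier are selected at the peak Matthews
    correlation coefficient. Includes a synthetic-matrix generator with
    planted ground truth and a command-line interface for the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ranger,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
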