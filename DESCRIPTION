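Package: psntopo
Title: Patient Similarity Networks, Topological Features and Outcome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds Patient Similarity Networks (PSNs) from patient-by-feature
    omics matrices using WGCNA-style soft thresholding of Pearson correlations,
    fuses networks across data sources with Similarity Network Fusion, extracts
    four families of node-topological features (twelve centrality metrics
    including iterative variants, module-membership indicators from spectral and
    stochastic block model clustering, biased-random-walk node embeddings, and
    network-diffusion signatures), and trains LDA / random forest / SVM
    classifiers on them to predict binary clinical endpoints, integrating model
    predictions by weighted voting. Includes a synthetic multi-omics cohort
    generator with planted class signal so the whole pipeline can be exercised
    and validated without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    MASS,
    randomForest,
    e1071,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
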