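Package: lfqmarker
Title: Consensus Biomarker Discovery from Label-Free Proteomics by
    Mutual Information, Network Propagation and SVM Feature Addition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes protein biomarker candidates that discriminate
    breast-cancer metastasis classes (no metastasis, late metastasis,
    early metastasis) from a log2 label-free quantification (LFQ)
    abundance matrix. Proteins are ranked by class-balanced,
    tercile-discretized mutual information with insulated-diffusion
    network-propagation scores on a protein-protein interaction network
    used to break ties; features are then selected per leave-one-out
    fold by recursive feature addition under an RBF-kernel support
    vector machine, and proteins selected in several folds form the
    consensus biomarker set. Includes completeness filtering and
    k-nearest-neighbor imputation of missing intensities, readers for
    plain and MaxQuant proteinGroups-style matrices and STRING-style
    edge lists, and a synthetic-cohort generator with planted markers
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    e1071,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
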