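Package: neuralign
Title: Inter-Subject Correlation, Conversation-Induced Neural Alignment, and
    Directed Neural Influence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how group conversation aligns brain activity.
    Computes voxel-wise pairwise inter-subject correlation (ISC) of BOLD time
    series, models conversation-induced change in ISC with group-membership
    predictor matrices and subject-wise permutation inference, applies
    cluster-extent multiple-comparisons correction, quantifies directed
    ego-to-alter neural influence and its dependence on social-network
    centrality (eigenvector centrality, Burt constraint brokerage, and a PCA
    composite), and runs the companion behavioral and linguistic analyses
    (city-block survey distances, survey influence, Gini turn-taking
    inequality, word-stem regressions). A synthetic-cohort generator with
    known ground truth makes every stage testable end to end without access
    to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
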