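Package: npskin
Title: In Silico Modeling of Nanoparticle Skin Penetration Depth and Routes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A quantitative structure-property relationship (QSPR) pipeline
    for predicting the skin penetration depth of nanoparticles from particle,
    skin and experimental-condition descriptors. Provides a documented CSV
    data model with derived particle geometry and mass-weighted stratum
    corneum lipid properties, chained-equation imputation of missing
    descriptors, random and rational data splitting (Kennard-Stone, k-means
    with elbow selection, Kohonen self-organizing maps), a multi-classifier
    selection grid (decision tree, random forest, k-nearest neighbours,
    PLS-DA, kernel SVM) evaluated by accuracy and Cohen's kappa, variable
    importance in projection (VIP) scores and grouped permutation importance,
    a convex-hull applicability domain in principal-component space,
    generation of large in-silico nanoparticle populations with
    Kruskal-Wallis and Dunn post hoc per-layer descriptor analysis, skin
    parameter perturbation scenarios that attribute penetration routes, and
    cross-species skin similarity comparisons. A synthetic data generator
    with a planted, hair-follicle-dominated labeling rule makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    kernlab,
    nnet,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
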