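Package: shapdyn
Title: Temporal Feature-Attribution Dynamics for Pre-Death Patient States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes how a decedent cohort's internal state evolves over the
    final months of life from irregular laboratory time series. Builds one
    gradient-boosted tree mortality classifier per prediction horizon (state n
    days before death versus the same patients' state 168 days before death),
    computes exact per-feature Shapley attributions in double precision for each
    model, and assembles max-scaled mean-attribution trajectories ("SHAP
    behaviors") across horizons. Attribution vectors immediately before death
    drive hierarchical patient stratification (Ward linkage, Euclidean distance,
    elbow/silhouette model selection) and 2-D embeddings (UMAP, t-SNE, PCA) of
    time-stacked patient states, with a raw-laboratory-value comparison arm. A
    synthetic decedent-cohort generator with planted latent subtypes, terminal
    drift, irregular visit schedules and missingness makes the whole pipeline
    testable without access to any real electronic health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    xgboost,
    jsonlite,
    yaml,
    cluster,
    pROC,
    uwot,
    Rtsne
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
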