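Package: linefc
Title: Line-Graph Neural Networks for Task-Induced Functional Connectivity Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts task-induced changes in static functional connectivity
    (FC) from baseline fMRI data using graph neural networks trained on line
    graphs, in which each functional correlation becomes a node. Provides a
    synthetic cohort simulator with planted, learnable connectivity effects;
    Spearman FC estimation with Bonferroni-corrected group thresholding and a
    subject participation filter; the line-graph transformation with attribute
    propagation; four message-passing architectures (GCN and GraphSAGE, each
    on the traditional ROI graph and on the line graph) implemented from
    first principles with analytic gradients and Adam; and a five-fold
    cross-validation harness with mean-predictor benchmarks, Wilcoxon
    signed-rank and paired t comparisons, and Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
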