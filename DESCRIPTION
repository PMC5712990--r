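Package: grangerlearn
Title: Supervised Classification-Based Detection of Granger Causality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects Granger-causal interactions between multivariate time
    series by casting causal-graph recovery as a supervised classification
    problem. Labeled trials are simulated from a multivariate autoregressive
    (MAR) model driven by enumerated binary causal graphs with controlled
    additive MAR noise, mapped into a feature space of lagged-regression
    scores over all causality scenarios (cause-subset/effect pairs), and
    classified either cell-by-cell (CBC, one binary classifier per graph
    entry) or jointly (MBC, one multiclass classifier over all graphs).
    Includes a from-scratch conditional Geweke time-domain baseline with
    asymptotic significance testing, pooled ROC/AUC and cost-sensitive
    confusion-matrix evaluation, and scripted replication of the simulation
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
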