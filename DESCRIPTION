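Package: gasselect
Title: Gas-Solubility and Aquila Metaheuristic Feature Selection for
    Clinical Outcome Classification
Version: 0.1.0
Authors@R:
    person("gasselect", "maintainers", email = "gasselect@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for multi-class clinical outcome
    prediction driven by two physics- and nature-inspired metaheuristics:
    Henry gas solubility optimization (HGSO), in which candidate solutions
    are gas particles whose solubility under Henry's law pulls them toward
    cluster and swarm bests, and the Aquila optimizer (AQO), which switches
    from exploration to exploitation at two thirds of the iteration budget.
    Continuous positions are binarized into feature masks and scored by a
    weighted combination of holdout misclassification and subset size.
    Includes a registry of base classifiers (k-NN, random forest,
    C4.5-style tree, single-hidden-layer neural network, RBF SVM) and a
    soft-voting RF-SVM double classifier, macro-averaged confusion-matrix
    metrics, an exact Wilcoxon signed-rank comparison, a synthetic
    neurosurgical-style tabular data generator with planted informative
    features, and a configuration-driven experiment grid runner with trace
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
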