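Package: boolfeat
Title: Interpretable Boolean Feature Learning for Clinical Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves small Boolean-logic feature representations of tabular
    clinical data by genetic programming under joint Pareto optimization of
    balanced logistic loss and representation complexity. Candidate
    representations are typed expression trees over the operators
    {<, >, AND, OR, NOT} with comparison thresholds learned by Gini impurity;
    a logistic model is fit on the evolved features, the result is simplified
    by correlation pruning and subtree deletion within a prediction-drift
    tolerance, and a concise final model is selected from the Pareto archive
    by validation balanced log-loss (optionally robustly over restarts).
    Includes discrimination metrics (average precision, AUROC), repeated
    cross-validation and variant-ablation harnesses, synthetic planted-rule
    and EHR-like cohort generators, and a command-line interface producing
    human-readable threshold-rule reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
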