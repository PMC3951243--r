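Package: caspian
Title: Causal Gene-Network Inference by Subspace Pursuit and Granger Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers directed gene regulatory networks from multi-experiment
    expression time series. Sparse linear dependencies between time-lagged
    expression profiles are recovered with the greedy Subspace Pursuit
    algorithm and its list variant (List-SP), and candidate regulators are
    pruned with conditional Granger-causality F-tests on nested least-squares
    models. Includes a prior-knowledge ("scaffold") variant that regresses out
    trusted regulators before inference, a synthetic-network simulator with
    stable linear dynamics for benchmarking, edge-level evaluation metrics
    (sensitivity, precision, accuracy, F-measure), and multiplicity-ratio
    confidence scores over randomized gene-panel runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
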