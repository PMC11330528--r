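Package: switchRL
Title: Belief-State Reinforcement Learning and Prediction-Error Neuron
    Analysis for Cross-Modal Task-Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a cross-modal (visual/olfactory) block-switching
    go/no-go task as a discrete-step reinforcement-learning environment,
    implements a tabular SARSA agent and a belief-state agent whose context
    belief is driven by a noise-corrupted block-mismatch signal, and fits
    both models to transition-aligned lick-probability curves by grid search
    with local refinement under cross-validation. Includes behavioural
    summary statistics (behavioural d-prime, switching speed with fluke
    exclusion, one-shot proportions, prediction-error amplitude by
    transition outcome), event-aligned calcium-imaging analysis (dF/F with a
    running-minimum baseline, three-epoch prediction-error neuron
    classification, sustained-significance detection, population decoding,
    percentile-bootstrap proportion intervals, a ridge encoding model), and
    synthetic behavioural and calcium data generators with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
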