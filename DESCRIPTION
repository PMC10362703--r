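Package: rlcausal
Title: Causal Discovery for Risk-Factor Tables by Reinforcement Learning with
    Inverse-Information-Entropy Edge Strengths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score-based causal structure learning for continuous risk-factor
    tables. A self-attention encoder and a pairwise decoder parameterise a
    distribution over directed graphs; graphs are sampled, scored by a
    decomposable Gaussian BIC with a trace-exponential acyclicity penalty, and
    the policy is improved by actor-critic policy gradients until the
    maximum-reward directed acyclic graph is found. Discovered edges are then
    annotated with an inverse-information-entropy causal strength computed from
    a spacing (Vasicek-type) differential-entropy estimator, and weak edges are
    pruned. Includes a linear structural-equation benchmark generator,
    structural Hamming distance evaluation, tidy() and glance() methods,
    ggplot2 autoplot() methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
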