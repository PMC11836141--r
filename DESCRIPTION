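Package: srmpt
Title: Storage-Retrieval Multinomial Processing Tree Analysis of Waking-Rest
    Memory Experiments
Version: 0.1.0
Authors@R:
    person("srmpt", "developers", email = "srmpt@example.org", role = c("aut", "cre"))
Description: Tools for decomposing recall and recognition memory performance
    into latent storage and retrieval processes with multinomial processing
    tree (MPT) models. Implements an EQN model parser, aggregated
    maximum-likelihood estimation with G-squared goodness of fit and nested
    model comparison, hierarchical Bayesian latent-trait estimation with
    convergence diagnostics and posterior-predictive checks, behavioral
    scoring with MAD-based outlier screening, one-way ANOVA with planned
    contrasts, noncentral-F power analysis, and a synthetic experiment
    generator for the three-condition (waking rest, social media, vocabulary
    learning) post-encoding design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
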