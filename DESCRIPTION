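Package: motivrl
Title: Reinforcement Learning with Motivational Salience
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reinforcement-learning agents whose rewards are
    modulated by internal motivational drives. Provides motivation-aware
    temporal-difference learning with small neural-network function
    approximators, a four-resource grid-world task with analytic strategy
    rates and an addiction variant, a transport-network routing task with a
    shortest-tour oracle, a two-level manager-agent hierarchy that infers
    motivation dynamics, a recurrent value network for Pavlovian conditioning
    with positive and negative motivation blocks, and a population-analysis
    pipeline (PCA plus hierarchical clustering, weight correlations, and a
    push-pull connectivity summary) for comparing model units with recordings
    from the ventral pallidum.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
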