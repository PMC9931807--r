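Package: bcanet
Title: Bayesian Coherence Analysis for Neural Microcircuit Structure Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns undirected functional microcircuits from binary spike or
    continuous calcium-imaging activity matrices by node-wise Markov blanket
    discovery. Each node is treated as the leaf of a Bayesian network whose
    parent set is optimized by greedy hill-climbing under a BDeu (binary) or
    BIC (linear-Gaussian) family score; the per-node blankets are combined
    into a single undirected graph. Includes exact small-model Ising
    machinery, a Metropolis-Hastings Ising sampler, a leaky integrate-and-fire
    network simulator with a shared-parent ground-truth graph, Gaussian Markov
    network sampling, correlation and L1-logistic-regression baselines with
    AND/OR ensembles, structure-recovery evaluation (TPR/FPR), and a
    microcircuit subtype pipeline (Sorensen-Dice similarity, multi-level
    modularity clustering, representative graphs, centrality contrasts).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    glmnet,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
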