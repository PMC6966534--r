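Package: cloneMig
Title: Inference and Evaluation of Tumor Clone Migration Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the migration history of tumor clones
    between a primary tumor and its metastases from a clone phylogeny and the
    tumor-site locations of sampled clones. Implements a parsimony approach
    (Sankoff dynamic programming with lexicographic minimization of migrations,
    comigrations and seeding sources, with optional polytomy resolution) and a
    Bayesian ancestral-site approach (equal-rate discrete-state Markov model with
    exact marginal posteriors by belief propagation and a Gibbs MCMC sampler,
    root-constrained through a germline outgroup). Includes a perfect-phylogeny
    reconstructor for homoplasy-free binary clone genotypes, a simulator of
    metastatic seeding under monoclonal, polyclonal, multisource and reseeding
    scenarios with known true migration graphs, and an evaluation framework
    (precision/recall/F1 over migration-graph edges, path-type error
    decomposition, grouped significance tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
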