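Package: EFDMreg
Title: Extended Flexible Dirichlet-Multinomial Models for Microbiome Counts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distribution theory and Bayesian regression for overdispersed
    multivariate count data arising in microbiome studies. Implements the
    extended flexible Dirichlet-multinomial (EFDM) family -- a structured
    mixture of Dirichlet-multinomial components whose barycenters are pulled
    toward simplex vertices -- together with its flexible Dirichlet-multinomial
    (FDM) and Dirichlet-multinomial (DM) sub-models. Provides exact log
    probability mass functions, closed-form moments and inter-/intraclass
    correlations, reproducible samplers, a multinomial-logit mean regression
    estimated by adaptive-Metropolis MCMC with weakly informative priors,
    spike-and-slab variable selection with marginalized inclusion indicators,
    WAIC model comparison, posterior-predictive zero-handling metrics and
    Kullback-Leibler divergence, taxa correlation networks, and simulation
    scenario generators with a replication-study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    nnet,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Regression, Bayesian, Software
RoxygenNote: 7.3.3
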