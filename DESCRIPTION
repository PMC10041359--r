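Package: dpmclust
Title: Bayesian Cluster Analysis with Dirichlet Process Mixtures and
    Decision-Theoretic Partition Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based and loss-based Bayesian cluster analysis with full
    uncertainty quantification over the space of partitions.  Fits Dirichlet
    process location-scale mixtures of Gaussians by collapsed Gibbs sampling
    with a conjugate normal-inverse-gamma (normal-inverse-Wishart) base
    measure and data-dependent hyperparameters, and a generalized-Bayes
    (Gibbs) posterior over fixed-k partitions under the k-means loss.
    Posterior draws are summarized by the posterior similarity matrix and by
    decision-theoretic point estimates: the MAP partition (0-1 loss), the
    Binder-loss partition, and the variation-of-information partition, each
    obtained by candidate search over MCMC draws and hierarchical-clustering
    cuts followed by greedy refinement.  Credible balls quantify uncertainty
    around any point estimate.  Includes seeded synthetic-data generators
    (standard normal, uniform on the unit disk, finite Gaussian mixtures) and
    a simulation-study driver comparing estimators of the number of clusters
    under model misspecification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
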