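#' Loss specification for generalized-Bayes clustering
#'
#' The Gibbs (loss-based) posterior over partitions is
#' `pi(z | y) ∝ exp(-lambda * loss(z, y)) * pi(z)`, with the prior uniform
#' over set partitions into exactly `k` non-empty clusters.  The implemented
#' discrepancy is the k-means loss: the total within-cluster sum of squared
#' Euclidean distances to the cluster means, so the MAP of this posterior is
#' the (global) k-means solution.
#'
#' @param k fixed number of clusters (`1 <= k <= n`).
#' @param lambda positive learning rate scaling the loss; there is no
#'   universal default — `1` is a reasonable starting point on standardized
#'   data, and larger values concentrate the posterior on the loss minimizer.
#' @return an object of class `"loss_spec"`.
#' @export
loss_spec <- function(k, lambda = 1) {
  stopifnot(length(k) == 1L, k >= 1, k == round(k),
            length(lambda) == 1L, is.finite(lambda), lambda > 0)
  structure(list(k = as.integer(k), lambda = as.numeric(lambda),
                 discrepancy = "squared-euclidean-to-cluster-mean"),
            class = "loss_spec")
}

#' k-means loss of a partition
#'
#' Total within-cluster sum of squared Euclidean distances to the cluster
#' means: `sum_j sum_{i: z_i = j} ||y_i - ybar_j||^2`.
#'
#' @param z partition (or allocation vector) of the rows of `data`.
#' @param data dataset (numeric matrix).
#' @return non-negative number; 0 for the all-singletons partition.
#' @export
kmeans_loss <- function(z, data) {
  z <- as_partition(z)
  data <- as.matrix(data)
  if (length(z) != nrow(data))
    stop("partition length and number of observations differ")
  zi <- as.integer(z)
  centers <- rowsum(data, zi) / as.vector(cluster_sizes(z))
  sum((data - centers[zi, , drop = FALSE])^2)
}

#' Sample the Gibbs posterior over fixed-k partitions
#'
#' Single-site Gibbs sampler on allocation labels `1..k` whose stationary
#' distribution is `exp(-lambda * kmeans_loss(z)) ` times the uniform prior
#' on partitions with exactly `k` non-empty clusters.  A move that would
#' empty a cluster is infeasible, so an observation alone in its cluster
#' keeps its label; on the label space this realizes the uniform prior over
#' labelled partitions using all `k` labels, which induces the uniform prior
#' over the corresponding set partitions.
#'
#' @param data dataset (numeric matrix).
#' @param spec a [loss_spec()].
#' @param config an [mcmc_config()].
#' @return a `partition_samples` object with canonical draws.
#' @export
sample_gibbs_posterior <- function(data, spec, config = mcmc_config()) {
  data <- as.matrix(data)
  n <- nrow(data)
  stopifnot(inherits(spec, "loss_spec"), inherits(config, "mcmc_config"))
  k <- spec$k
  if (k > n) stop("k must not exceed the number of observations")
  lambda <- spec$lambda

  draws <- with_gen_seed(config$seed, {
    # random feasible start: k seed observations get distinct labels
    z <- sample.int(k, n, replace = TRUE)
    z[sample.int(n, k)] <- sample.int(k, k)

    counts <- tabulate(z, nbins = k)
    sums <- rowsum(data, factor(z, levels = seq_len(k)))

    n_keep <- (config$iterations - config$burn_in) %/% config$thinning
    draws <- matrix(0L, n_keep, n)
    stored <- 0L
    for (t in seq_len(config$iterations)) {
      for (i in seq_len(n)) {
        a <- z[i]
        if (counts[a] == 1L) next  # moving i would empty cluster a
        yi <- data[i, ]
        counts[a] <- counts[a] - 1L
        sums[a, ] <- sums[a, ] - yi
        # cost of adding i to each cluster given the removal
        mu <- sums / counts
        dev2 <- rowSums((mu - rep(yi, each = k))^2)
        add <- counts / (counts + 1) * dev2
        w <- exp(-lambda * (add - min(add)))
        j <- sample.int(k, 1L, prob = w)
        counts[j] <- counts[j] + 1L
        sums[j, ] <- sums[j, ] + yi
        z[i] <- j
      }
      if (t > config$burn_in &&
          (t - config$burn_in) %% config$thinning == 0L && stored < n_keep) {
        stored <- stored + 1L
        draws[stored, ] <- as.integer(canonicalize(z))
      }
    }
    draws
  })
  new_partition_samples(draws,
                        meta = list(sampler = "single-site Gibbs (loss posterior, fixed k)",
                                    spec = spec, config = config))
}

#' MAP of the Gibbs loss posterior
#'
#' Runs [sample_gibbs_posterior()], takes the lowest-loss draw, and refines
#' it with Hartigan-style reassignment passes (each observation moves to the
#' cluster that most reduces the k-means loss, moves emptying a cluster
#' excluded) until no improvement.  Under the k-means loss the exact MAP is
#' the global k-means solution; the returned partition is the best local
#' optimum found along the chain.
#'
#' @inheritParams sample_gibbs_posterior
#' @param max_sweeps cap on refinement passes.
#' @return an `estimator_result` (see [estimate()]): the partition, its loss
#'   and its number of clusters.
#' @export
map_gibbs_posterior <- function(data, spec, config = mcmc_config(),
                                max_sweeps = 50) {
  data <- as.matrix(data)
  samples <- sample_gibbs_posterior(data, spec, config)
  losses <- apply(samples$draws, 1L, kmeans_loss, data = data)
  z <- as.integer(samples$draws[which.min(losses), ])
  k <- spec$k
  n <- nrow(data)

  counts <- tabulate(z, nbins = k)
  sums <- rowsum(data, factor(z, levels = seq_len(k)))
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      a <- z[i]
      if (counts[a] == 1L) next
      yi <- data[i, ]
      counts[a] <- counts[a] - 1L
      sums[a, ] <- sums[a, ] - yi
      mu <- sums / counts
      dev2 <- rowSums((mu - rep(yi, each = k))^2)
      add <- counts / (counts + 1) * dev2
      j <- which.min(add)
      if (j != a) changed <- TRUE
      counts[j] <- counts[j] + 1L
      sums[j, ] <- sums[j, ] + yi
      z[i] <- j
    }
    if (!changed) break
  }
  zc <- canonicalize(z)
  new_estimator_result(zc, "kmeans", kmeans_loss(zc, data))
}
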