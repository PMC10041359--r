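#' MCMC configuration
#'
#' @param iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before storing draws (`< iterations`).
#' @param thinning keep every `thinning`-th post-burn-in sweep.
#' @param seed integer seed controlling the whole chain.
#' @return an object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(iterations = 10000, burn_in = 1000, thinning = 1,
                        seed = 1) {
  stopifnot(iterations >= 1, burn_in >= 0, thinning >= 1,
            length(seed) == 1L, is.finite(seed))
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

new_partition_samples <- function(draws, meta) {
  stopifnot(is.matrix(draws), nrow(draws) >= 1L)
  structure(list(draws = draws, n = ncol(draws), meta = meta),
            class = "partition_samples")
}

#' Posterior partition draws
#'
#' Container for an ordered set of MCMC partition draws: an integer matrix
#' with one canonical allocation vector per row, the number of observations,
#' and sampler metadata (`meta`).
#'
#' @param x object to test or print.
#' @return `is_partition_samples()` a logical; `n_draws()` the number of
#'   stored draws.
#' @export
is_partition_samples <- function(x) inherits(x, "partition_samples")

#' @rdname is_partition_samples
#' @param samples a `partition_samples` object.
#' @export
n_draws <- function(samples) {
  stopifnot(is_partition_samples(samples))
  nrow(samples$draws)
}

#' @export
print.partition_samples <- function(x, ...) {
  ks <- apply(x$draws, 1L, max)
  cat(sprintf("partition_samples: %d draws on %d observations\n",
              nrow(x$draws), x$n))
  cat(sprintf("  clusters per draw: min %d / median %g / max %d\n",
              min(ks), stats::median(ks), max(ks)))
  if (!is.null(x$meta$sampler))
    cat("  sampler:", x$meta$sampler, "\n")
  invisible(x)
}

# wrap a bare draw matrix (rows = draws) as partition_samples, canonicalizing
as_partition_samples <- function(draws, meta = list()) {
  if (is_partition_samples(draws)) return(draws)
  draws <- as.matrix(draws)
  draws <- t(apply(draws, 1L, function(r) as.integer(canonicalize(r))))
  new_partition_samples(draws, meta)
}

#' Collapsed Gibbs sampler for the DP Gaussian mixture
#'
#' Samples the posterior over partitions of a Dirichlet process
#' location-scale mixture of Gaussians with conjugate base measure, using the
#' marginal (collapsed) Gibbs sampler: component parameters are integrated
#' out and each observation is reassigned in turn from its full conditional,
#' with weights proportional to `n_j * pred(y_i | cluster j)` for existing
#' clusters and `alpha * pred(y_i | empty)` for a new one, where `pred` is
#' the closed-form conjugate predictive density.
#'
#' @param data dataset (numeric matrix, observations in rows).
#' @param prior an [nig_prior()]; `NULL` uses [default_hyperparams()] with
#'   its default prior guess of 2 clusters.
#' @param alpha positive DP concentration parameter.
#' @param config an [mcmc_config()].
#' @param init initial allocation vector; default all observations in one
#'   cluster.
#' @return a `partition_samples` object; `$draws` has one canonical
#'   allocation vector per kept sweep, `floor((iterations - burn_in) /
#'   thinning)` of them.
#' @export
run_mcmc <- function(data, prior = NULL, alpha = 1,
                     config = mcmc_config(), init = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 1L) stop("data must contain at least one observation")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            inherits(config, "mcmc_config"))
  if (is.null(prior)) prior <- default_hyperparams(data)
  stopifnot(inherits(prior, "nig_prior"))
  if (ncol(data) != prior$d) stop("dimension mismatch between data and prior")
  if (is.null(init)) init <- rep(1L, n)
  init <- as.integer(as_partition(init))
  if (length(init) != n) stop("init must allocate every observation")

  draws <- with_gen_seed(config$seed,
    .cpp_dp_gibbs(data, prior$mu0, prior$c, prior$nu,
                  as.matrix(prior$delta2), alpha,
                  config$iterations, config$burn_in, config$thinning,
                  init))
  new_partition_samples(draws,
                        meta = list(sampler = "collapsed Gibbs (conjugate DP Gaussian mixture)",
                                    alpha = alpha, prior = prior,
                                    config = config))
}

#' Concentration-parameter schedule
#'
#' Returns a fixed concentration value unchanged, or the sample-size
#' dependent choice `alpha = 1 / log(n)` (natural logarithm) under the
#' `"1/log(n)"` rule.
#'
#' @param rule a positive number (fixed alpha) or the string `"1/log(n)"`
#'   (aliases `"logn"`, `"1/log n"`).
#' @param n sample size (`>= 2` for the logarithmic rule).
#' @return a positive scalar.
#' @export
alpha_schedule <- function(rule, n) {
  if (is.numeric(rule)) {
    stopifnot(length(rule) == 1L, rule > 0)
    return(as.numeric(rule))
  }
  if (is.character(rule) && rule %in% c("1/log(n)", "logn", "1/log n")) {
    stopifnot(length(n) == 1L, is.finite(n))
    if (n <= 1) stop("the 1/log(n) rule needs n >= 2")
    return(1 / log(n))
  }
  stop("rule must be a positive number or \"1/log(n)\"")
}

#' Read and write partition draws as delimited text
#'
#' One draw per row, comma-separated integer labels; metadata is not stored.
#'
#' @param samples a `partition_samples` object.
#' @param path file path.
#' @export
write_draws <- function(samples, path) {
  stopifnot(is_partition_samples(samples))
  utils::write.table(samples$draws, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  as_partition_samples(as.matrix(utils::read.table(path, sep = ",",
                                                   header = FALSE)))
}
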