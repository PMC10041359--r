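#' Conjugate normal-inverse-gamma / normal-inverse-Wishart base measure
#'
#' Prior for the cluster-specific location and scale of a Gaussian kernel.
#' In one dimension,
#' \deqn{\mu_j \mid \sigma_j^2 \sim N(\mu_0, \sigma_j^2 / c), \qquad
#'       \sigma_j^2 \sim IG(\nu/2, \delta^2/2),}
#' and for `d > 1` the direct normal-inverse-Wishart generalization with
#' degrees of freedom `nu` and scale matrix `delta2`
#' (\eqn{\Sigma_j \sim IW(\nu, \Delta)}, \eqn{\mu_j \mid \Sigma_j \sim
#' N(\mu_0, \Sigma_j / c)}).
#'
#' @param mu0 prior mean location (length-`d` numeric).
#' @param c positive scale on the prior-mean precision; values below 1 put
#'   more prior variance between cluster means than within clusters.
#' @param nu inverse-gamma / inverse-Wishart degrees of freedom
#'   (`nu > d - 1`; `nu > d + 1` gives the scale a finite mean).
#' @param delta2 inverse-gamma scale (scalar, `d = 1`) or inverse-Wishart
#'   scale matrix (`d x d` positive definite).
#' @return an object of class `"nig_prior"`.
#' @seealso [default_hyperparams()] for the data-dependent choice used by
#'   default throughout the package.
#' @export
nig_prior <- function(mu0, c, nu, delta2) {
  mu0 <- as.numeric(mu0)
  d <- length(mu0)
  stopifnot(is.numeric(c), length(c) == 1L, c > 0,
            is.numeric(nu), length(nu) == 1L, nu > 0)
  if (d > 1L && nu <= d - 1)
    stop("nu must exceed d - 1 for a proper inverse-Wishart")
  delta2 <- as.matrix(delta2)
  if (!all(dim(delta2) == c(d, d)))
    stop("delta2 must be a scalar (d = 1) or a d x d matrix")
  ev <- eigen((delta2 + t(delta2)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop("delta2 must be positive (positive definite)")
  structure(list(mu0 = mu0, c = c, nu = nu, delta2 = delta2, d = d),
            class = "nig_prior")
}

#' @export
print.nig_prior <- function(x, ...) {
  cat(sprintf("normal-inverse-%s base measure (d = %d)\n",
              if (x$d == 1L) "gamma" else "Wishart", x$d))
  cat("  mu0    :", paste(signif(x$mu0, 4), collapse = ", "), "\n")
  cat("  c      :", x$c, "\n")
  cat("  nu     :", x$nu, "\n")
  cat("  delta2 :", paste(signif(diag(x$delta2), 4), collapse = ", "),
      if (x$d > 1L) "(diagonal shown)" else "", "\n")
  invisible(x)
}

#' Data-dependent hyperparameters for the Gaussian base measure
#'
#' The empirical-Bayes recipe used by default: `mu0` is the empirical mean,
#' `c = 0.01`, `nu = d + 2` (the smallest integer degrees of freedom giving
#' the marginal t prior on the cluster mean a finite variance), and `delta2`
#' is the empirical variance divided by `k_hat^2` (for `d > 1`, the diagonal
#' matrix of empirical variances divided by `k_hat^2`), where `k_hat` is a
#' prior guess of the number of clusters.  The empirical variance is an upper
#' bound for the within-cluster variance; dividing by `k_hat^2` concentrates
#' prior mass on within-cluster scales consistent with `k_hat` clusters.
#'
#' @param data dataset (numeric matrix, `n >= 2` rows).
#' @param k_hat prior guess of the number of clusters (default 2).
#' @return an [nig_prior()].
#' @export
default_hyperparams <- function(data, k_hat = 2) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("at least two observations are needed")
  stopifnot(k_hat >= 1)
  d <- ncol(data)
  v <- apply(data, 2L, stats::var)
  nig_prior(mu0 = colMeans(data), c = 0.01, nu = d + 2,
            delta2 = diag(v / k_hat^2, d))
}

# prior constants reused by every marginal-likelihood evaluation
prior_consts <- function(prior) {
  d <- prior$d
  list(d = d,
       logc = log(prior$c),
       lmvg_nu = lmvgamma(prior$nu / 2, d),
       logdet_delta2 = as.numeric(determinant(prior$delta2,
                                              logarithm = TRUE)$modulus))
}

# log multivariate gamma function
lmvgamma <- function(a, d) {
  (d * (d - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

#' Log marginal likelihood of a cluster under the conjugate Gaussian model
#'
#' Integrates the Gaussian likelihood of the rows of `cluster_data` against
#' the normal-inverse-gamma (-Wishart) base measure in closed form.  An empty
#' cluster returns 0 (the empty product).
#'
#' @param cluster_data numeric matrix of the observations in one cluster
#'   (0 or more rows, `d` columns matching the prior).
#' @param prior an [nig_prior()].
#' @return the log marginal likelihood (a single number).
#' @export
log_marginal_likelihood <- function(cluster_data, prior) {
  stopifnot(inherits(prior, "nig_prior"))
  y <- as.matrix(cluster_data)
  if (nrow(y) == 0L) return(0)
  if (ncol(y) != prior$d) stop("dimension mismatch between data and prior")
  m <- nrow(y)
  s <- colSums(y)
  ss <- crossprod(y)
  lml_from_stats(m, s, ss, prior, prior_consts(prior))
}

# marginal likelihood from sufficient statistics (m, sum, sum of outer
# products); pc = prior_consts(prior)
lml_from_stats <- function(m, s, ss, prior, pc) {
  if (m == 0L) return(0)
  d <- pc$d
  cn <- prior$c + m
  nun <- prior$nu + m
  ybar <- s / m
  dev <- ybar - prior$mu0
  lambda_n <- prior$delta2 + (ss - m * tcrossprod(ybar)) +
    (prior$c * m / cn) * tcrossprod(dev)
  logdet_n <- if (d == 1L) log(lambda_n[1L]) else
    as.numeric(determinant(lambda_n, logarithm = TRUE)$modulus)
  -(m * d / 2) * log(pi) + (d / 2) * (pc$logc - log(cn)) +
    lmvgamma(nun / 2, d) - pc$lmvg_nu +
    (prior$nu / 2) * pc$logdet_delta2 - (nun / 2) * logdet_n
}

#' Unnormalized log posterior of a partition under the DP Gaussian mixture
#'
#' `log pi(z | y) = log EPPF(z; alpha) + sum_j log m(y_j)` up to the
#' normalizing constant, where `m(y_j)` is the closed-form marginal
#' likelihood of cluster `j`.  Depends on `z` only through the induced set
#' partition.
#'
#' @param z partition (or allocation vector) of the rows of `data`.
#' @param data dataset (numeric matrix).
#' @param prior an [nig_prior()].
#' @param alpha positive DP concentration parameter.
#' @return unnormalized log posterior (single number).
#' @export
log_posterior_partition <- function(z, data, prior, alpha) {
  z <- as_partition(z)
  data <- as.matrix(data)
  if (length(z) != nrow(data))
    stop("partition length and number of observations differ")
  pc <- prior_consts(prior)
  lp <- dp_eppf_log(z, dp_prior(alpha))
  for (j in seq_len(n_clusters(z))) {
    yj <- data[as.integer(z) == j, , drop = FALSE]
    lp <- lp + lml_from_stats(nrow(yj), colSums(yj), crossprod(yj), prior, pc)
  }
  lp
}

# Full-conditional reassignment distribution of observation i given the rest
# of the partition (collapsed Gibbs update).  Returns the candidate label
# vector (existing clusters of z[-i], then a new singleton) and their
# probabilities.  Computed from marginal-likelihood ratios; used for
# transition-matrix checks and independent of the compiled sampler.
allocation_probs <- function(z, i, data, prior, alpha) {
  z <- as.integer(as_partition(z))
  data <- as.matrix(data)
  n <- length(z)
  stopifnot(i >= 1L, i <= n)
  pc <- prior_consts(prior)
  zm <- canonicalize(z[-i])          # clusters without observation i
  km <- n_clusters(zm)
  sizes <- cluster_sizes(zm)
  yi <- data[i, ]
  others <- data[-i, , drop = FALSE]
  logw <- numeric(km + 1L)
  for (j in seq_len(km)) {
    yj <- others[as.integer(zm) == j, , drop = FALSE]
    pred <- lml_from_stats(nrow(yj) + 1L, colSums(yj) + yi,
                           crossprod(yj) + tcrossprod(yi), prior, pc) -
      lml_from_stats(nrow(yj), colSums(yj), crossprod(yj), prior, pc)
    logw[j] <- log(sizes[j]) + pred
  }
  logw[km + 1L] <- log(alpha) +
    lml_from_stats(1L, yi, tcrossprod(yi), prior, pc)
  p <- exp(logw - logsumexp(logw))
  # candidate full label vectors (not canonicalized: caller may canonicalize)
  cand <- lapply(seq_len(km + 1L), function(j) {
    znew <- integer(n)
    znew[-i] <- as.integer(zm)
    znew[i] <- j
    znew
  })
  list(candidates = cand, probs = p / sum(p))
}
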