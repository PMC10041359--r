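#' Dirichlet process partition prior
#'
#' The exchangeable partition probability function (EPPF) induced by a
#' Dirichlet process with concentration parameter `alpha`:
#' \deqn{\pi(z) = \frac{\Gamma(\alpha)}{\Gamma(\alpha + n)}\,
#'       \alpha^{k} \prod_{j=1}^{k} \Gamma(n_j),}
#' which depends on the allocation vector only through the cluster sizes
#' \eqn{n_j}, hence is invariant to cluster relabelling and to permutation of
#' the observations.  Larger `alpha` favours more clusters a priori.
#'
#' @param alpha positive DP concentration parameter.
#' @return an object of class `"dp_prior"`.
#' @export
dp_prior <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  structure(list(alpha = alpha), class = "dp_prior")
}

#' @export
print.dp_prior <- function(x, ...) {
  cat(sprintf("Dirichlet process partition prior (EPPF), alpha = %g\n",
              x$alpha))
  invisible(x)
}

#' Log prior probability of a partition under the DP EPPF
#'
#' @param z a partition (or allocation vector).
#' @param prior a [dp_prior()], or a positive number taken as `alpha`.
#' @return log prior probability (a single number, `<= 0`).
#' @examples
#' dp_eppf_log(c(1, 1), dp_prior(1))   # log(1/2)
#' @export
dp_eppf_log <- function(z, prior) {
  if (is.numeric(prior)) prior <- dp_prior(prior)
  stopifnot(inherits(prior, "dp_prior"))
  z <- as_partition(z)
  a <- prior$alpha
  n <- length(z)
  sz <- cluster_sizes(z)
  lgamma(a) - lgamma(a + n) + length(sz) * log(a) + sum(lgamma(sz))
}
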