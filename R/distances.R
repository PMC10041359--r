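#' Binder distance between two partitions
#'
#' Counts the observation pairs on which two partitions disagree about
#' co-clustering, i.e. `sum_{i<i'} (1(z1_i = z1_i') - 1(z2_i = z2_i'))^2`.
#' With unequal pair weights `(a, b)` a pair clustered together in `z1` but
#' apart in `z2` costs `a`, and the reverse costs `b`; the default `(1, 1)`
#' is the symmetric disagreement count.
#'
#' @param z1,z2 partitions (or allocation vectors) of equal length.
#' @param weights length-2 numeric: cost of (together-in-z1, apart-in-z2)
#'   and (apart-in-z1, together-in-z2) disagreements.
#' @return non-negative number; 0 iff the partitions coincide.
#' @export
binder_distance <- function(z1, z2, weights = c(1, 1)) {
  z1 <- as_partition(z1); z2 <- as_partition(z2)
  if (length(z1) != length(z2))
    stop("partitions have different lengths")
  stopifnot(length(weights) == 2L, all(weights >= 0))
  # pair counts from the contingency table: sum over cells of C(m_ab, 2)
  k1 <- n_clusters(z1); k2 <- n_clusters(z2)
  m <- tabulate((as.integer(z1) - 1L) * k2 + as.integer(z2), k1 * k2)
  tog_both <- sum(choose(m, 2))
  tog1 <- sum(choose(cluster_sizes(z1), 2))
  tog2 <- sum(choose(cluster_sizes(z2), 2))
  weights[1L] * (tog1 - tog_both) + weights[2L] * (tog2 - tog_both)
}

#' Variation of information between two partitions
#'
#' The information-theoretic metric `VI(z1, z2) = H(z1) + H(z2) - 2 I(z1, z2)`
#' with empirical cluster frequencies.  It is a true metric on set partitions
#' (symmetric, zero only at equality, triangle inequality).  Entropies are in
#' natural logarithms by default.
#'
#' @param z1,z2 partitions (or allocation vectors) of equal length.
#' @param base logarithm base; `exp(1)` gives nats, `2` gives bits.
#' @return non-negative number.
#' @export
vi_distance <- function(z1, z2, base = exp(1)) {
  z1 <- as_partition(z1); z2 <- as_partition(z2)
  if (length(z1) != length(z2))
    stop("partitions have different lengths")
  n <- length(z1)
  k1 <- n_clusters(z1); k2 <- n_clusters(z2)
  # joint cluster-pair counts via a flat index (faster than table())
  m <- tabulate((as.integer(z1) - 1L) * k2 + as.integer(z2), k1 * k2) / n
  p1 <- cluster_sizes(z1) / n
  p2 <- cluster_sizes(z2) / n
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  v <- 2 * h(m) - h(p1) - h(p2)      # 2 * joint entropy - H1 - H2
  max(v, 0) / log(base)
}
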