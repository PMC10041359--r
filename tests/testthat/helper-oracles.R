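# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: set partitions are enumerated by a block-growing
# recursion (not restricted-growth strings), distances by direct pair /
# entropy computation, and the DP prior by the sequential Chinese-restaurant
# product.

# all set partitions of 1..n as a list of block lists
oracle_partition_blocks <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(list(list(1L)))
  smaller <- oracle_partition_blocks(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# blocks -> allocation vector (labels by order of block's smallest element)
oracle_blocks_to_labels <- function(blocks, n) {
  z <- integer(n)
  ord <- order(vapply(blocks, function(b) min(as.integer(b)), 0L))
  for (j in seq_along(ord)) z[blocks[[ord[j]]]] <- j
  z
}

oracle_all_partitions <- function(n) {
  t(vapply(oracle_partition_blocks(n), oracle_blocks_to_labels,
           integer(n), n = n))
}

# pairwise-disagreement count by explicit pair loop
oracle_binder <- function(z1, z2) {
  n <- length(z1)
  s <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    s <- s + abs((z1[i] == z1[j]) - (z2[i] == z2[j]))
  s
}

# VI from entropies of the empirical joint distribution (nats)
oracle_vi <- function(z1, z2) {
  n <- length(z1)
  joint <- table(z1, z2) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(rowSums(joint)) + ent(colSums(joint)) +
    2 * (ent(joint) - ent(rowSums(joint)) - ent(colSums(joint)))
}

# DP prior probability of an allocation via the sequential CRP product
oracle_crp_prob <- function(z, alpha) {
  p <- 1
  for (i in seq_along(z)) {
    if (i == 1L) next
    prev <- z[seq_len(i - 1L)]
    nj <- sum(prev == z[i])
    p <- p * (if (nj > 0) nj else alpha) / (i - 1 + alpha)
  }
  p
}

# total-variation distance between a frequency table over partition keys and
# an exact probability vector on the same keys
oracle_tv <- function(draw_keys, exact_keys, exact_probs) {
  freq <- table(factor(draw_keys, levels = exact_keys)) / length(draw_keys)
  0.5 * sum(abs(as.numeric(freq) - exact_probs))
}

partition_keys <- function(mat) apply(mat, 1L, paste, collapse = ",")

random_labels <- function(n, kmax = 3L) {
  as.integer(canonicalize(sample.int(kmax, n, replace = TRUE)))
}
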