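#' Partitions of a finite set
#'
#' A partition of `n` observations is stored as an allocation vector of
#' 1-based cluster labels in *canonical* (order-of-appearance) form: the
#' cluster of observation 1 is labelled 1, and each subsequent new label is
#' the smallest unused integer.  Two allocation vectors describe the same set
#' partition if and only if their canonical forms are identical, so all
#' equality tests in the package compare canonical labels.
#'
#' @param raw_labels integer (or integer-like) vector of cluster labels, one
#'   per observation.  Labels may be arbitrary; only the induced grouping
#'   matters.
#' @return An object of class `"partition"`: the canonical integer label
#'   vector, with attributes `k` (number of clusters) and `sizes` (cluster
#'   sizes `n_1, ..., n_k` in label order).
#' @examples
#' canonicalize(c(2, 1, 2))   # labels 1 2 1, k = 2
#' canonicalize(c(5, 5, 5))   # labels 1 1 1, k = 1
#' @export
canonicalize <- function(raw_labels) {
  if (length(raw_labels) == 0L)
    stop("a partition needs at least one observation")
  if (anyNA(raw_labels))
    stop("labels must not contain NA")
  raw <- as.integer(round(as.numeric(raw_labels)))
  z <- match(raw, unique(raw))
  new_partition(z)
}

# Internal constructor: `z` must already be canonical.
new_partition <- function(z) {
  k <- max(z)
  structure(z,
            k = k,
            sizes = tabulate(z, nbins = k),
            class = "partition")
}

#' @rdname canonicalize
#' @param x object to coerce or test.
#' @export
as_partition <- function(x) {
  if (inherits(x, "partition")) x else canonicalize(x)
}

#' @rdname canonicalize
#' @export
is_partition <- function(x) inherits(x, "partition")

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition of %d observations into %d cluster%s (sizes: %s)\n",
              length(x), n_clusters(x), if (n_clusters(x) == 1L) "" else "s",
              paste(cluster_sizes(x), collapse = ", ")))
  print(as.integer(x))
  invisible(x)
}

#' Number of clusters and cluster sizes of a partition
#'
#' @param z a `partition` (or anything `as_partition()` accepts).
#' @return `n_clusters()` the number of non-empty clusters; `cluster_sizes()`
#'   the integer vector of cluster sizes in canonical label order.
#' @export
n_clusters <- function(z) {
  z <- as_partition(z)
  attr(z, "k")
}

#' @rdname n_clusters
#' @export
cluster_sizes <- function(z) {
  z <- as_partition(z)
  attr(z, "sizes")
}

#' Test whether two allocation vectors describe the same set partition
#'
#' @param z1,z2 allocation vectors or `partition` objects of equal length.
#' @return logical scalar.
#' @export
same_partition <- function(z1, z2) {
  z1 <- as_partition(z1); z2 <- as_partition(z2)
  length(z1) == length(z2) && all(as.integer(z1) == as.integer(z2))
}

#' Enumerate all set partitions of n elements
#'
#' Generates every set partition of `{1, ..., n}` as canonical allocation
#' vectors via restricted-growth strings.  The number of rows is the Bell
#' number B(n), so this is only feasible for small `n` (exact posterior
#' enumeration, exhaustive loss minimization, normalization checks).
#'
#' @param n number of elements (1 to 12).
#' @param k optional: restrict to partitions with exactly `k` non-empty
#'   clusters (Stirling number S(n, k) of them).
#' @return integer matrix, one canonical allocation vector per row.
#' @export
enumerate_partitions <- function(n, k = NULL) {
  stopifnot(n >= 1, n <= 12)
  out <- list()
  cnt <- 0L
  z <- integer(n)
  recurse <- function(i, kmax) {
    if (i > n) {
      if (is.null(k) || kmax == k) {
        cnt <<- cnt + 1L
        out[[cnt]] <<- z
      }
      return(invisible())
    }
    for (j in seq_len(kmax + 1L)) {
      z[i] <<- j
      recurse(i + 1L, max(kmax, j))
    }
  }
  z[1L] <- 1L
  recurse(2L, 1L)
  do.call(rbind, out[seq_len(cnt)])
}

#' Read and write partitions as single-column integer text files
#'
#' @param z a partition (or allocation vector).
#' @param path file path.
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a `partition`.
#' @export
write_partition <- function(z, path) {
  z <- as_partition(z)
  utils::write.table(data.frame(label = as.integer(z)), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  canonicalize(utils::read.table(path, header = FALSE)[[1L]])
}
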