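#' Seeded synthetic-data generators
#'
#' Generators for the two benchmark sampling designs used throughout the
#' package — a standard normal in one dimension (a single "true" cluster that
#' a location-scale Gaussian mixture nevertheless over-partitions as `n`
#' grows) and the uniform distribution on the unit disk in two dimensions (a
#' misspecified target that a Gaussian mixture approximates with arbitrary
#' convex pieces) — plus generic finite Gaussian mixtures with known
#' ground-truth labels.  Every generator is a pure function of its arguments
#' and `seed`; replicate `r` of a simulation uses `seed = base_seed + r`.
#'
#' @param n number of observations (>= 1).
#' @param seed integer seed.
#' @return a numeric matrix with `n` rows (observations) and `d` columns,
#'   of class `"dataset"`.
#' @name synthetic
NULL

new_dataset <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L) stop("dataset must be non-empty")
  if (!all(is.finite(x))) stop("dataset entries must all be finite")
  class(x) <- c("dataset", "matrix", "array")
  x
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("dataset: %d observations, %d dimension%s\n", nrow(x), ncol(x),
              if (ncol(x) == 1L) "" else "s"))
  y <- x; class(y) <- NULL
  print(utils::head(y, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @rdname synthetic
#' @export
gen_standard_normal <- function(n, seed) {
  check_size(n)
  new_dataset(with_gen_seed(seed, matrix(stats::rnorm(n), ncol = 1L)))
}

#' @rdname synthetic
#' @param boundary if `TRUE`, sample from the circle boundary (radius 1)
#'   rather than the solid disk.  The default is the solid disk, sampled by
#'   the inverse-CDF radius transform (radius `sqrt(u)` for uniform `u`,
#'   with a uniform angle).
#' @export
gen_uniform_disk <- function(n, seed, boundary = FALSE) {
  check_size(n)
  new_dataset(with_gen_seed(seed, {
    theta <- stats::runif(n, 0, 2 * pi)
    r <- if (boundary) rep(1, n) else sqrt(stats::runif(n))
    cbind(r * cos(theta), r * sin(theta))
  }))
}

#' Finite Gaussian mixture specification
#'
#' @param weights probability vector over components (must sum to 1 within
#'   1e-12).
#' @param means list of component mean vectors (all of dimension `d`), or a
#'   numeric vector for `d = 1`.
#' @param covariances list of `d x d` symmetric positive-definite matrices,
#'   or a numeric vector of variances for `d = 1`.
#' @return an object of class `"mixture_spec"`.
#' @export
mixture_spec <- function(weights, means, covariances) {
  weights <- as.numeric(weights)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  if (is.numeric(means)) means <- lapply(means, function(m) m)
  means <- lapply(means, as.numeric)
  if (is.numeric(covariances)) covariances <- as.list(covariances)
  covariances <- lapply(covariances, function(s) as.matrix(s))
  J <- length(weights)
  if (length(means) != J || length(covariances) != J)
    stop("weights, means and covariances must have the same length")
  d <- length(means[[1L]])
  for (j in seq_len(J)) {
    if (length(means[[j]]) != d) stop("all means must have the same dimension")
    S <- covariances[[j]]
    if (!all(dim(S) == c(d, d)) || !isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
      stop("covariances must be symmetric d x d matrices")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariances must be positive definite")
  }
  structure(list(weights = weights, means = means, covariances = covariances,
                 J = J, d = d),
            class = "mixture_spec")
}

#' @rdname synthetic
#' @param spec a [mixture_spec()].
#' @return `gen_gaussian_mixture()` returns a list with elements `data` (a
#'   dataset) and `truth` (the generating allocation as a `partition`).
#' @export
gen_gaussian_mixture <- function(n, spec, seed) {
  check_size(n)
  stopifnot(inherits(spec, "mixture_spec"))
  out <- with_gen_seed(seed, {
    comp <- sample.int(spec$J, n, replace = TRUE, prob = spec$weights)
    chol_list <- lapply(spec$covariances, chol)
    y <- matrix(stats::rnorm(n * spec$d), n, spec$d)
    for (j in unique(comp)) {
      idx <- which(comp == j)
      y[idx, ] <- y[idx, , drop = FALSE] %*% chol_list[[j]] +
        rep(spec$means[[j]], each = length(idx))
    }
    list(y = y, comp = comp)
  })
  list(data = new_dataset(out$y), truth = canonicalize(out$comp))
}

check_size <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a positive integer")
  invisible(TRUE)
}

# evaluate expr under the given seed, restoring the caller's RNG state
with_gen_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' Read and write datasets as headerless delimited text
#'
#' One observation per row, columns separated by `sep`; no header, no row
#' names.
#'
#' @param data a dataset (numeric matrix).
#' @param path file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @export
write_dataset <- function(data, path, sep = ",") {
  utils::write.table(unclass(as.matrix(data)), path, sep = sep,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, sep = ",") {
  new_dataset(as.matrix(utils::read.table(path, sep = sep, header = FALSE)))
}
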