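#' Posterior similarity matrix
#'
#' Entry (i, i') is the fraction of posterior draws in which observations i
#' and i' share a cluster — the Monte-Carlo estimate of their co-clustering
#' probability.  Symmetric, unit diagonal, entries between 0 and 1.
#'
#' @param samples a `partition_samples` object (or a draw matrix, one
#'   allocation vector per row).
#' @return an `n x n` numeric matrix of class `"psm"`.
#' @export
posterior_similarity <- function(samples) {
  samples <- as_partition_samples(samples)
  if (n_draws(samples) < 1L) stop("at least one draw is required")
  P <- .cpp_psm(samples$draws)
  class(P) <- c("psm", "matrix", "array")
  P
}

#' @export
print.psm <- function(x, ...) {
  cat(sprintf("posterior similarity matrix (%d x %d)\n", nrow(x), ncol(x)))
  off <- x[upper.tri(x)]
  cat(sprintf("  off-diagonal co-clustering probabilities: min %.3f / mean %.3f / max %.3f\n",
              min(off), mean(off), max(off)))
  invisible(x)
}

#' Posterior-expected Binder loss of a candidate partition
#'
#' Computed exactly from the posterior similarity matrix:
#' `sum_{i<i'} [ 1(z_i = z_i') (1 - p_ii') + (1 - 1(z_i = z_i')) p_ii' ]`.
#' This equals the Monte-Carlo average of [binder_distance()] between the
#' candidate and the draws that produced the PSM (an identity, not an
#' approximation).
#'
#' @param candidate partition (or allocation vector).
#' @param psm posterior similarity matrix from [posterior_similarity()].
#' @return non-negative number.
#' @export
expected_binder <- function(candidate, psm) {
  z <- as.integer(as_partition(candidate))
  psm <- as.matrix(psm)
  if (length(z) != nrow(psm)) stop("candidate and PSM sizes differ")
  same <- outer(z, z, "==")
  ut <- upper.tri(psm)
  sum(ifelse(same[ut], 1 - psm[ut], psm[ut]))
}

#' Posterior-expected variation of information of a candidate partition
#'
#' In `"exact-average"` mode, the Monte-Carlo mean of [vi_distance()] between
#' the candidate and every draw.  In `"psm-lower-bound"` mode, the
#' Jensen-swapped criterion of the expected VI computed from the posterior
#' similarity matrix alone (natural logarithms):
#' `(1/n) sum_i [ log n_{z_i} + log sum_j p_ij - 2 log sum_{j in cl(i)} p_ij ]`.
#' The PSM criterion is far cheaper and is what the VI point estimate
#' minimizes by default.
#'
#' @param candidate partition (or allocation vector).
#' @param samples `partition_samples`; required for `"exact-average"`.
#' @param psm posterior similarity matrix; required for `"psm-lower-bound"`.
#' @param mode which expectation to compute.
#' @return non-negative number (nats).
#' @export
expected_vi <- function(candidate, samples = NULL, psm = NULL,
                        mode = c("psm-lower-bound", "exact-average")) {
  mode <- match.arg(mode)
  z <- as_partition(candidate)
  if (mode == "exact-average") {
    if (is.null(samples)) stop("exact-average mode needs the draws")
    samples <- as_partition_samples(samples)
    if (length(z) != samples$n) stop("candidate and draws sizes differ")
    mean(apply(samples$draws, 1L, vi_distance, z2 = z))
  } else {
    if (is.null(psm)) stop("psm-lower-bound mode needs the PSM")
    psm <- as.matrix(psm)
    zi <- as.integer(z)
    if (length(zi) != nrow(psm)) stop("candidate and PSM sizes differ")
    n <- length(zi)
    sizes <- tabulate(zi)
    s <- vapply(seq_len(n), function(i) sum(psm[i, zi == zi[i]]), 0)
    mean(log(sizes[zi]) + log(rowSums(psm)) - 2 * log(s))
  }
}

#' Candidate partitions for point-estimate search
#'
#' The union of (a) every distinct partition visited by the sampler and (b)
#' the cuts of an agglomerative hierarchical clustering of the observations
#' with dissimilarity `1 - PSM`, at every number of clusters from 1 to n.
#' All candidates are canonical and deduplicated; rows are sorted
#' lexicographically so that downstream ties break deterministically.
#'
#' @param samples a `partition_samples` object.
#' @param psm posterior similarity matrix (computed from `samples` if
#'   omitted).
#' @param linkage hierarchical-clustering linkage (`"average"` default, or
#'   `"complete"`).
#' @return integer matrix, one canonical allocation vector per row.
#' @export
candidate_set <- function(samples, psm = NULL,
                          linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  samples <- as_partition_samples(samples)
  if (is.null(psm)) psm <- posterior_similarity(samples)
  psm <- as.matrix(psm)
  n <- samples$n
  if (n >= 2L) {
    hc <- stats::hclust(stats::as.dist(1 - psm), method = linkage)
    cuts <- stats::cutree(hc, k = seq_len(n))         # n x n, column per k
    cuts <- t(apply(cuts, 2L, function(r) as.integer(canonicalize(r))))
  } else {
    cuts <- matrix(1L, 1L, 1L)
  }
  cands <- rbind(samples$draws, cuts)
  cands <- cands[!duplicated(apply(cands, 1L, partition_key)), , drop = FALSE]
  ord <- do.call(order, as.data.frame(cands))
  cands[ord, , drop = FALSE]
}

new_estimator_result <- function(partition, loss_name, objective) {
  partition <- as_partition(partition)
  structure(list(partition = partition, loss_name = loss_name,
                 objective = as.numeric(objective),
                 k = n_clusters(partition)),
            class = "estimator_result")
}

#' @export
print.estimator_result <- function(x, ...) {
  cat(sprintf("partition estimate (%s loss): k = %d, objective = %.6g\n",
              x$loss_name, x$k, x$objective))
  cat("  sizes:", paste(cluster_sizes(x$partition), collapse = ", "), "\n")
  invisible(x)
}

#' Greedy local search over partitions
#'
#' Repeated improvement sweeps on an arbitrary objective: in each sweep every
#' observation in turn takes its best objective-decreasing reassignment
#' (to any existing cluster or to a new singleton), then the best
#' objective-decreasing merge of two clusters is applied.  Stops when a sweep
#' changes nothing or after `max_sweeps` sweeps.  The returned objective is
#' never larger than the initial one.
#'
#' This generic version re-evaluates `objective` on whole partitions and is
#' meant for small problems and arbitrary objectives; [estimate()] uses
#' dedicated incremental versions of the same neighbourhood for its three
#' losses.
#'
#' @param init starting partition (or allocation vector).
#' @param objective function mapping a partition to a number (smaller is
#'   better).
#' @param max_sweeps cap on improvement sweeps.
#' @return the locally optimal `partition`.
#' @export
greedy_search <- function(init, objective, max_sweeps = 50) {
  z <- as.integer(as_partition(init))
  n <- length(z)
  best <- objective(canonicalize(z))
  eps <- 1e-9
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      labs <- unique(z[-i])
      targets <- c(labs[labs != z[i]],
                   if (sum(z == z[i]) > 1L) max(z) + 1L)
      for (lab in targets) {
        znew <- z; znew[i] <- lab
        val <- objective(canonicalize(znew))
        if (val < best - eps) {
          z <- znew; best <- val; changed <- TRUE
        }
      }
    }
    labs <- unique(z)
    if (length(labs) >= 2L) {
      pairs <- utils::combn(labs, 2L)
      for (p in seq_len(ncol(pairs))) {
        znew <- z; znew[znew == pairs[2L, p]] <- pairs[1L, p]
        val <- objective(canonicalize(znew))
        if (val < best - eps) {
          z <- znew; best <- val; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  canonicalize(z)
}

#' Decision-theoretic partition point estimates
#'
#' Minimizes the posterior-expected loss over [candidate_set()] (MCMC draws
#' plus hierarchical-clustering cuts of `1 - PSM`) and then refines the best
#' candidate by greedy search (single-observation reassignments and cluster
#' merges).  Three losses are supported:
#' * `"zero-one"` — the MAP partition; the objective is the negative
#'   unnormalized log posterior [log_posterior_partition()], so `data`,
#'   `prior` and `alpha` must be supplied.
#' * `"binder"` — posterior-expected Binder loss, exact from the PSM.
#' * `"vi"` — posterior-expected variation of information; by default the
#'   PSM-based criterion (`vi_mode = "psm-lower-bound"`), optionally the
#'   exact Monte-Carlo average (`"exact-average"`, costly).
#'
#' @param samples a `partition_samples` object.
#' @param loss_name `"zero-one"`, `"binder"` or `"vi"`.
#' @param data,prior,alpha model context, required for `"zero-one"`
#'   (`prior = NULL` falls back to [default_hyperparams()]).
#' @param psm posterior similarity matrix (computed if omitted).
#' @param vi_mode VI expectation mode, see [expected_vi()].
#' @param max_sweeps cap on greedy refinement sweeps.
#' @param candidates optional precomputed [candidate_set()] matrix, to share
#'   one candidate search across several losses.
#' @return an `estimator_result`: `partition`, `loss_name`, `objective`
#'   (value of the minimized criterion) and `k`.
#' @export
estimate <- function(samples, loss_name = c("vi", "binder", "zero-one"),
                     data = NULL, prior = NULL, alpha = NULL, psm = NULL,
                     vi_mode = c("psm-lower-bound", "exact-average"),
                     max_sweeps = 50, candidates = NULL) {
  loss_name <- match.arg(loss_name)
  vi_mode <- match.arg(vi_mode)
  samples <- as_partition_samples(samples)
  if (is.null(psm)) psm <- posterior_similarity(samples)
  psm <- as.matrix(psm)

  if (loss_name == "zero-one") {
    if (is.null(data) || is.null(alpha))
      stop("the MAP (zero-one loss) estimate needs data and alpha")
    data <- as.matrix(data)
    if (is.null(prior)) prior <- default_hyperparams(data)
  }

  cands <- if (is.null(candidates)) candidate_set(samples, psm)
           else candidates
  scores <- switch(loss_name,
    "binder" = .cpp_expected_binder(cands, psm),
    "vi" = if (vi_mode == "psm-lower-bound") .cpp_vi_lb(cands, psm)
           else apply(cands, 1L, expected_vi, samples = samples,
                      mode = "exact-average"),
    "zero-one" = -.cpp_log_post(cands, data, prior$mu0, prior$c, prior$nu,
                                as.matrix(prior$delta2), alpha))
  init <- canonicalize(cands[which.min(scores), ])

  refined <- switch(loss_name,
    "binder" = greedy_psm_binder(init, psm, max_sweeps),
    "vi" = if (vi_mode == "psm-lower-bound")
             greedy_psm_vilb(init, psm, max_sweeps)
           else greedy_search(init, function(z)
             expected_vi(z, samples = samples, mode = "exact-average"),
             max_sweeps),
    "zero-one" = greedy_logpost(init, data, prior, alpha, max_sweeps))

  objective <- switch(loss_name,
    "binder" = expected_binder(refined, psm),
    "vi" = expected_vi(refined, samples = samples, psm = psm, mode = vi_mode),
    "zero-one" = -log_posterior_partition(refined, data, prior, alpha))
  new_estimator_result(refined, loss_name, objective)
}

#' Mode of the marginal posterior on the number of clusters
#'
#' The most frequent cluster count among the draws; ties break toward the
#' smaller count.
#'
#' @param samples a `partition_samples` object.
#' @return positive integer.
#' @export
marginal_mode_k <- function(samples) {
  samples <- as_partition_samples(samples)
  if (n_draws(samples) < 1L) stop("at least one draw is required")
  ks <- apply(samples$draws, 1L, max)
  counts <- tabulate(ks)
  which.max(counts)   # first maximum = smallest k among ties
}

#' Credible ball around a partition estimate
#'
#' The smallest metric ball centred at `center` containing at least a
#' `level` fraction of the posterior draws: the radius is the
#' `ceiling(level * M)`-th order statistic of the M draw-to-center distances.
#'
#' @param samples a `partition_samples` object.
#' @param center centre partition (typically an [estimate()] result's
#'   `$partition`).
#' @param metric `"vi"` or `"binder"`.
#' @param level coverage level in (0, 1).
#' @return an object of class `"credible_ball"` with fields `center`,
#'   `metric`, `level`, `radius`.
#' @export
credible_ball <- function(samples, center, metric = c("vi", "binder"),
                          level = 0.95) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  samples <- as_partition_samples(samples)
  center <- as_partition(center)
  if (length(center) != samples$n) stop("center and draws sizes differ")
  distfun <- if (metric == "vi") vi_distance else binder_distance
  d <- apply(samples$draws, 1L, distfun, z2 = center)
  radius <- sort(d)[ceiling(level * length(d))]
  structure(list(center = center, metric = metric, level = level,
                 radius = radius),
            class = "credible_ball")
}

#' @export
print.credible_ball <- function(x, ...) {
  cat(sprintf("%.0f%% credible ball (%s metric): radius %.4g around k = %d clusters\n",
              100 * x$level, x$metric, x$radius, n_clusters(x$center)))
  invisible(x)
}
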