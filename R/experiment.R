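#' Simulation-study grid
#'
#' Describes a full factorial comparison of partition estimators: a sampling
#' design (`"standard-normal"`, one dimension, or `"uniform-disk"`, two
#' dimensions — in both, the true clustering is a single cluster and the DP
#' Gaussian mixture is misspecified for the disk), a set of sample sizes, a
#' set of DP concentration values (numbers, or the string `"1/log(n)"` for
#' the sample-size dependent rule), a number of replicate datasets per cell,
#' and the MCMC settings.
#'
#' Replicate `r` draws its data with seed `base_seed + r`, and each
#' (example, n, alpha) cell runs its sampler with seed
#' `base_seed + 20000 + 977 * cell_index + r`, so every cell is independently
#' reproducible.
#'
#' @param example `"standard-normal"` or `"uniform-disk"`.
#' @param n_values integer vector of sample sizes (all `>= 2`).
#' @param alpha_values list (or vector) of positive numbers and/or
#'   `"1/log(n)"`.
#' @param replicates datasets per cell.
#' @param base_seed integer base seed.
#' @param mcmc an [mcmc_config()] (its `seed` field is overridden per cell).
#' @param k_hat prior guess of the cluster count fed to
#'   [default_hyperparams()].  The study default is 1: both benchmark designs
#'   have a single true cluster, so the prior within-cluster scale is the
#'   empirical variance itself.  Dividing the scale by a larger `k_hat^2`
#'   concentrates the prior on within-cluster variances far below the data
#'   spread, which is exactly the too-small-scale regime in which the MAP
#'   partition fragments into arbitrary convex pieces.
#' @return an object of class `"experiment_grid"`.
#' @export
experiment_grid <- function(example = c("standard-normal", "uniform-disk"),
                            n_values = c(100, 500),
                            alpha_values = list(0.5, 2, "1/log(n)"),
                            replicates = 10,
                            base_seed = 1,
                            mcmc = mcmc_config(iterations = 3000,
                                               burn_in = 500),
                            k_hat = 1) {
  example <- match.arg(example)
  n_values <- as.integer(n_values)
  stopifnot(all(n_values >= 2), replicates >= 1,
            inherits(mcmc, "mcmc_config"))
  if (!is.list(alpha_values)) alpha_values <- as.list(alpha_values)
  structure(list(example = example, n_values = n_values,
                 alpha_values = alpha_values,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), mcmc = mcmc,
                 k_hat = k_hat),
            class = "experiment_grid")
}

alpha_label <- function(a) if (is.character(a)) "1/log(n)" else format(a)

#' Run an estimator-comparison simulation study
#'
#' For every cell (n, alpha) and replicate r of the grid: generate a dataset,
#' fit the DP Gaussian mixture by collapsed Gibbs sampling with
#' data-dependent hyperparameters, and record the number of clusters found by
#' four estimators — the mode of the marginal posterior on k, the MAP
#' partition (0-1 loss), the Binder partition and the VI partition.  The
#' whole study is a pure function of the grid (including `base_seed`).
#'
#' @param grid an [experiment_grid()].
#' @param verbose print one line per completed cell.
#' @return a long-format data frame of class `"k_table"` with columns
#'   `example`, `n`, `alpha` (label), `alpha_value`, `replicate`,
#'   `estimator` (`"mode"`, `"map"`, `"binder"`, `"vi"`) and `k`.
#' @export
run_experiment <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- expand.grid(n = grid$n_values,
                       a = seq_along(grid$alpha_values),
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]
    a_spec <- grid$alpha_values[[cells$a[ci]]]
    alpha <- alpha_schedule(a_spec, n)
    for (r in seq_len(grid$replicates)) {
      data_seed <- grid$base_seed + r
      data <- switch(grid$example,
        "standard-normal" = gen_standard_normal(n, seed = data_seed),
        "uniform-disk" = gen_uniform_disk(n, seed = data_seed))
      prior <- default_hyperparams(data, k_hat = grid$k_hat)
      cfg <- mcmc_config(iterations = grid$mcmc$iterations,
                         burn_in = grid$mcmc$burn_in,
                         thinning = grid$mcmc$thinning,
                         seed = grid$base_seed + 20000L + 977L * ci + r)
      samples <- run_mcmc(data, prior, alpha, cfg)
      psm <- posterior_similarity(samples)
      cands <- candidate_set(samples, psm)
      ks <- c(
        mode = marginal_mode_k(samples),
        map = estimate(samples, "zero-one", data = data, prior = prior,
                       alpha = alpha, psm = psm, candidates = cands)$k,
        binder = estimate(samples, "binder", psm = psm,
                          candidates = cands)$k,
        vi = estimate(samples, "vi", psm = psm, candidates = cands)$k)
      rows[[length(rows) + 1L]] <- data.frame(
        example = grid$example, n = n, alpha = alpha_label(a_spec),
        alpha_value = alpha, replicate = r,
        estimator = names(ks), k = as.integer(ks),
        row.names = NULL)
    }
    if (verbose)
      message(sprintf("cell %d/%d done (n = %d, alpha = %s)",
                      ci, nrow(cells), n, alpha_label(a_spec)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("k_table", "data.frame")
  out
}

#' Summarize an estimator-comparison table
#'
#' One row per (example, n, alpha, estimator) cell with the five-number
#' summary (min, lower quartile, median, upper quartile, max) and the mode of
#' the estimated number of clusters across replicates — the numeric
#' equivalent of a box plot per cell.  Mode ties break toward the smaller k.
#'
#' @param table a `k_table` from [run_experiment()].
#' @return a data frame, one row per cell.
#' @export
summarize_experiment <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            all(c("example", "n", "alpha", "estimator", "k") %in%
                  names(table)))
  key <- interaction(table$example, table$n, table$alpha, table$estimator,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(table)), key), function(idx) {
    k <- table$k[idx]
    counts <- tabulate(k)
    q <- stats::quantile(k, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(example = table$example[idx[1L]], n = table$n[idx[1L]],
               alpha = table$alpha[idx[1L]],
               estimator = table$estimator[idx[1L]],
               replicates = length(k),
               min = min(k), q1 = q[1L], median = q[2L], q3 = q[3L],
               max = max(k), mode = which.max(counts),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out[order(out$example, out$n, out$alpha, out$estimator), , drop = FALSE]
}
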