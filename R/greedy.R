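# Incremental greedy refinement for the three point-estimate objectives.
# Same neighbourhood as greedy_search() (single-observation reassignment to
# any existing cluster or a new singleton, then the best cluster merge, per
# sweep), but with O(1)-per-move objective deltas instead of full
# re-evaluation.  All three are verified against greedy_search() on small
# instances in the test suite.

.greedy_eps <- 1e-9

# expected Binder loss: objective = const + sum over within-cluster pairs of
# (1 - 2 p_ij); all deltas are group sums of Q = 1 - 2 * psm
greedy_psm_binder <- function(init, psm, max_sweeps = 50) {
  z <- as.integer(as_partition(init))
  n <- length(z)
  Q <- 1 - 2 * psm
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      g <- rowsum(Q[i, ], z)
      labs <- as.integer(rownames(g))
      w <- g[, 1L]
      own <- which(labs == z[i])
      w[own] <- w[own] - Q[i, i]              # exclude the j = i term
      deltas <- w - w[own]
      deltas[own] <- Inf
      delta_new <- if (sum(z == z[i]) > 1L) -w[own] else Inf
      best <- which.min(deltas)
      if (delta_new < deltas[best] && delta_new < -.greedy_eps) {
        z[i] <- max(z) + 1L
        changed <- TRUE
      } else if (deltas[best] < -.greedy_eps) {
        z[i] <- labs[best]
        changed <- TRUE
      }
    }
    labs <- sort(unique(z))
    if (length(labs) >= 2L) {
      B <- rowsum(t(rowsum(Q, z)), z)         # between-cluster block sums
      diag(B) <- Inf
      m <- arrayInd(which.min(B), dim(B))
      if (B[m] < -.greedy_eps) {
        z[z == labs[m[2L]]] <- labs[m[1L]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  canonicalize(z)
}

# PSM-based VI criterion: per-observation terms log n_{z_i} - 2 log s_i with
# s_i = sum over i's cluster of p_ij; the log row-sum term is constant.
# State s is updated incrementally after each accepted move.
greedy_psm_vilb <- function(init, psm, max_sweeps = 50) {
  z <- as.integer(as_partition(init))
  n <- length(z)
  s <- vapply(seq_len(n), function(i) sum(psm[i, z == z[i]]), 0)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      labs <- sort(unique(z))
      f <- match(z, labs)
      k <- length(labs)
      cs <- tabulate(f, k)
      a <- f[i]
      na <- cs[a]
      p <- psm[i, ]
      sig <- rowsum(p, f)[, 1L]               # cross sums to each cluster
      vadd <- log(s + p) - log(s)
      Tadd <- rowsum(vadd, f)[, 1L]
      amask <- f == a & seq_len(n) != i
      side_a <- if (na > 1L)
        (na - 1) * (log(na - 1) - log(na)) -
          2 * sum(log(s[amask] - p[amask]) - log(s[amask]))
      else 0
      base_i <- -log(na) + 2 * log(s[i])
      deltas <- log(cs + 1) - 2 * log(sig + 1) + base_i + side_a +
        cs * (log(cs + 1) - log(cs)) - 2 * Tadd
      deltas[a] <- Inf
      delta_new <- if (na > 1L) base_i + side_a else Inf
      best <- which.min(deltas)
      move_new <- delta_new < deltas[best]
      move_val <- if (move_new) delta_new else deltas[best]
      if (move_val < -.greedy_eps * n) {
        # update s for the affected members, then relabel i
        s[amask] <- s[amask] - p[amask]
        if (move_new) {
          s[i] <- 1
          z[i] <- max(z) + 1L
        } else {
          bmask <- f == best
          s[bmask] <- s[bmask] + p[bmask]
          s[i] <- sig[best] + 1
          z[i] <- labs[best]
        }
        changed <- TRUE
      }
    }
    labs <- sort(unique(z))
    k <- length(labs)
    if (k >= 2L) {
      f <- match(z, labs)
      cs <- tabulate(f, k)
      M <- t(rowsum(psm, f))                  # n x k cross sums
      best_val <- Inf; best_pair <- NULL; best_snew <- NULL; best_idx <- NULL
      for (g in seq_len(k - 1L)) for (h in seq(g + 1L, k)) {
        idx <- which(f == g | f == h)
        snew <- s[idx] + ifelse(f[idx] == g, M[idx, h], M[idx, g])
        val <- sum(log(cs[g] + cs[h]) - log(cs[f[idx]]) -
                     2 * log(snew) + 2 * log(s[idx]))
        if (val < best_val) {
          best_val <- val; best_pair <- c(g, h)
          best_snew <- snew; best_idx <- idx
        }
      }
      if (best_val < -.greedy_eps * n) {
        s[best_idx] <- best_snew
        z[z == labs[best_pair[2L]]] <- labs[best_pair[1L]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  canonicalize(z)
}

# MAP objective: maximize log EPPF + sum of cluster log marginal likelihoods,
# with per-cluster sufficient statistics and cached marginal likelihoods
greedy_logpost <- function(init, data, prior, alpha, max_sweeps = 50) {
  data <- as.matrix(data)
  z <- as.integer(as_partition(init))
  n <- length(z)
  d <- ncol(data)
  pc <- prior_consts(prior)
  k <- max(z)
  count <- tabulate(z, k)
  sums <- rowsum(data, factor(z, levels = seq_len(k)))
  ssq <- lapply(seq_len(k), function(g)
    crossprod(data[z == g, , drop = FALSE]))
  clml <- vapply(seq_len(k), function(g)
    lml_from_stats(count[g], sums[g, ], ssq[[g]], prior, pc), 0)

  drop_cluster <- function(g) {
    # move last cluster into slot g
    if (g != k) {
      z[z == k] <<- g
      count[g] <<- count[k]
      sums[g, ] <<- sums[k, ]
      ssq[[g]] <<- ssq[[k]]
      clml[g] <<- clml[k]
    }
    count <<- count[-k]; sums <<- sums[-k, , drop = FALSE]
    ssq[[k]] <<- NULL; clml <<- clml[-k]
    k <<- k - 1L
  }

  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      a <- z[i]
      yi <- data[i, ]
      yyi <- tcrossprod(yi)
      na <- count[a]
      lml_a_minus <- lml_from_stats(na - 1L, sums[a, ] - yi, ssq[[a]] - yyi,
                                    prior, pc)
      rem <- lml_a_minus - clml[a] +
        (if (na > 1L) lgamma(na - 1) - lgamma(na) else -log(alpha))
      lml1 <- lml_from_stats(1L, yi, yyi, prior, pc)
      gain <- rep(-Inf, k + 1L)
      lml_with <- numeric(k)
      for (g in seq_len(k)) {
        if (g == a) next
        lml_with[g] <- lml_from_stats(count[g] + 1L, sums[g, ] + yi,
                                      ssq[[g]] + yyi, prior, pc)
        gain[g] <- rem + lml_with[g] - clml[g] + log(count[g])
      }
      if (na > 1L) gain[k + 1L] <- rem + lml1 + log(alpha)
      best <- which.max(gain)
      if (gain[best] > .greedy_eps) {
        # remove i from a
        count[a] <- na - 1L
        sums[a, ] <- sums[a, ] - yi
        ssq[[a]] <- ssq[[a]] - yyi
        clml[a] <- lml_a_minus
        emptied <- count[a] == 0L
        if (best == k + 1L) {
          k <- k + 1L
          count[k] <- 1L
          sums <- rbind(sums, yi)
          ssq[[k]] <- yyi
          clml[k] <- lml1
          z[i] <- k
        } else {
          count[best] <- count[best] + 1L
          sums[best, ] <- sums[best, ] + yi
          ssq[[best]] <- ssq[[best]] + yyi
          clml[best] <- lml_with[best]
          z[i] <- best
        }
        if (emptied) drop_cluster(a)
        changed <- TRUE
      }
    }
    if (k >= 2L) {
      best_val <- .greedy_eps; best_pair <- NULL; best_lml <- 0
      for (g in seq_len(k - 1L)) for (h in seq(g + 1L, k)) {
        lml_gh <- lml_from_stats(count[g] + count[h], sums[g, ] + sums[h, ],
                                 ssq[[g]] + ssq[[h]], prior, pc)
        val <- lml_gh - clml[g] - clml[h] +
          lgamma(count[g] + count[h]) - lgamma(count[g]) -
          lgamma(count[h]) - log(alpha)
        if (val > best_val) {
          best_val <- val; best_pair <- c(g, h); best_lml <- lml_gh
        }
      }
      if (!is.null(best_pair)) {
        g <- best_pair[1L]; h <- best_pair[2L]
        z[z == h] <- g
        count[g] <- count[g] + count[h]
        sums[g, ] <- sums[g, ] + sums[h, ]
        ssq[[g]] <- ssq[[g]] + ssq[[h]]
        clml[g] <- best_lml
        if (h != k) z[z == k] <- h
        count[h] <- count[k]; sums[h, ] <- sums[k, ]
        ssq[[h]] <- ssq[[k]]; clml[h] <- clml[k]
        count <- count[-k]; sums <- sums[-k, , drop = FALSE]
        ssq[[k]] <- NULL; clml <- clml[-k]
        k <- k - 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  canonicalize(z)
}
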