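test_that("data-dependent hyperparameters follow the empirical recipe", {
  y <- matrix(c(0, 2, 4, 6), ncol = 1)   # sample variance 20/3
  pr <- default_hyperparams(y, k_hat = 2)
  expect_equal(pr$nu, 3)                  # d + 2
  expect_equal(pr$c, 0.01)
  expect_equal(pr$mu0, 3)
  expect_equal(pr$delta2[1, 1], var(c(0, 2, 4, 6)) / 4)

  # stated arithmetic case: variance 4, k_hat 2 -> delta2 = 1
  y2 <- matrix(scale(rnorm(50)) * 2, ncol = 1)  # exact sample variance 4
  expect_equal(default_hyperparams(y2, 2)$delta2[1, 1], 1, tolerance = 1e-12)

  u <- gen_uniform_disk(100, seed = 1)
  pr2 <- default_hyperparams(u, k_hat = 3)
  expect_equal(pr2$nu, 4)                 # d + 2 with d = 2
  expect_equal(pr2$mu0, colMeans(u))
  expect_equal(diag(pr2$delta2), apply(u, 2, var) / 9)
  expect_equal(pr2$delta2[1, 2], 0)

  expect_error(default_hyperparams(matrix(1), 2), "two observations")
  expect_error(nig_prior(0, c = -1, nu = 3, delta2 = 1))
  expect_error(nig_prior(c(0, 0), c = 1, nu = 0.5, delta2 = diag(2)),
               "exceed")
})

test_that("marginal likelihood matches quadrature and the Student-t predictive", {
  pr <- nig_prior(0.3, c = 0.5, nu = 3, delta2 = 1.2)

  expect_equal(log_marginal_likelihood(matrix(numeric(0), 0, 1), pr), 0)

  # single observation: integrate the NIG mixture numerically
  y0 <- 1.7
  quad <- integrate(function(s2v) sapply(s2v, function(s2) {
    m <- integrate(function(mu) dnorm(y0, mu, sqrt(s2)) *
                     dnorm(mu, 0.3, sqrt(s2 / 0.5)), -40, 40)$value
    b <- 1.2 / 2; a <- 3 / 2
    m * b^a / gamma(a) * s2^(-a - 1) * exp(-b / s2)
  }), 0, Inf)$value
  expect_equal(log_marginal_likelihood(matrix(y0), pr), log(quad),
               tolerance = 1e-6)

  # ... and the closed-form t marginal: y ~ t_nu(mu0, delta2 (c+1)/(c nu))
  s <- sqrt(1.2 * (0.5 + 1) / (0.5 * 3))
  expect_equal(log_marginal_likelihood(matrix(y0), pr),
               dt((y0 - 0.3) / s, df = 3, log = TRUE) - log(s),
               tolerance = 1e-12)

  # sequential decomposition: log m(y1, y2) = log m(y1) + log pred(y2 | y1),
  # with the predictive computed from the updated NIG parameters
  y1 <- 0.4; y2 <- -1.1
  c1 <- 0.5 + 1
  mu1 <- (0.5 * 0.3 + y1) / c1
  nu1 <- 3 + 1
  d21 <- 1.2 + (0.5 / c1) * (y1 - 0.3)^2
  s1 <- sqrt(d21 * (c1 + 1) / (c1 * nu1))
  pred <- dt((y2 - mu1) / s1, df = nu1, log = TRUE) - log(s1)
  expect_equal(log_marginal_likelihood(matrix(c(y1, y2)), pr),
               log_marginal_likelihood(matrix(y1), pr) + pred,
               tolerance = 1e-12)
})

test_that("bivariate marginal likelihood matches the multivariate-t marginal", {
  pr <- nig_prior(c(0.5, -1), c = 0.2, nu = 4,
                  delta2 = matrix(c(1.5, 0.3, 0.3, 0.8), 2))
  y <- c(0.9, -0.2)
  nu_t <- 4 - 2 + 1
  S <- pr$delta2 * (0.2 + 1) / (0.2 * nu_t)
  dev <- y - pr$mu0
  q <- drop(t(dev) %*% solve(S) %*% dev)
  logt <- lgamma((nu_t + 2) / 2) - lgamma(nu_t / 2) - log(nu_t * pi) -
    0.5 * determinant(S)$modulus[1] - ((nu_t + 2) / 2) * log(1 + q / nu_t)
  expect_equal(log_marginal_likelihood(matrix(y, 1, 2), pr), logt,
               tolerance = 1e-12)
})

test_that("partition log posterior assembles EPPF and cluster marginals", {
  set.seed(10)
  y <- matrix(rnorm(6), ncol = 1)
  pr <- default_hyperparams(y, 2)
  z <- c(1, 2, 1, 3, 2, 1)

  # invariant to relabelling
  expect_equal(log_posterior_partition(z, y, pr, 0.7),
               log_posterior_partition(c(3, 1, 3, 2, 1, 3), y, pr, 0.7))

  # dual-route assembly on every partition of 5 points
  y5 <- y[1:5, , drop = FALSE]
  parts <- enumerate_partitions(5)
  for (r in sample(nrow(parts), 10)) {
    zz <- parts[r, ]
    manual <- log(oracle_crp_prob(zz, 0.7)) +
      sum(vapply(unique(zz), function(g)
        log_marginal_likelihood(y5[zz == g, , drop = FALSE], pr), 0))
    expect_equal(log_posterior_partition(zz, y5, pr, 0.7), manual,
                 tolerance = 1e-10)
  }

  # exponentiating over all partitions gives a proper distribution
  lp <- apply(parts, 1L, log_posterior_partition, data = y5, prior = pr,
              alpha = 0.7)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))

  expect_error(log_posterior_partition(c(1, 1), y, pr, 1), "differ")
})

test_that("a far outlier prefers its own cluster under a tight prior scale", {
  y <- matrix(c(-0.1, 0, 0.1, 15), ncol = 1)
  pr <- nig_prior(mu0 = mean(y), c = 0.01, nu = 3, delta2 = 0.05)
  together <- log_posterior_partition(c(1, 1, 1, 1), y, pr, 1)
  split <- log_posterior_partition(c(1, 1, 1, 2), y, pr, 1)
  expect_gt(split, together)
})
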