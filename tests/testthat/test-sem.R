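# direct multivariate-normal log-density (small-J oracle)
dmvnorm_log <- function(y, mean, S) {
  k <- length(y)
  ch <- chol(S)
  z <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

test_that("marginal mean and covariance follow the path equations", {
  m <- sem_model(lambda = c(2, 0.5), mu = c(1, -0.3),
                 sigma_b = 0.5, sigma_t = 0.4, sigma_p = 0.2, sigma_r = 0.1)
  x <- c(1, 2)
  mg <- sem_marginal(m, x, J_p = 2, J_r = 2)
  expect_equal(mg$mean, c(3, 3, 3.4, 3.4))
  S <- mg$cov
  expect_equal(S[1, 1], 0.5^2 + 0.2^2)         # var(p)
  expect_equal(S[1, 2], 0.5^2)                 # cov(p, p')
  expect_equal(S[1, 3], 0.5^2)                 # cov(p, r)
  expect_equal(S[3, 3], 0.5^2 + 0.4^2 + 0.1^2) # var(r)
  expect_equal(S[3, 4], 0.5^2 + 0.4^2)         # cov(r, r')
  expect_equal(S, t(S))
  expect_true(all(eigen(S, only.values = TRUE)$values > 0))
})

test_that("marginal covariance matches Monte Carlo from the generative draws", {
  set.seed(42)
  m <- sem_model(c(1), c(0.5), 0.6, 0.3, 0.25, 0.15)
  X <- matrix(1, 50000, 1)
  sim <- sem_simulate(m, X, J_p = 2, J_r = 2)
  Y <- cbind(sim$p, sim$r)
  mg <- sem_marginal(m, 1, 2, 2)
  # MC SE of a covariance entry ~ var/sqrt(n); allow 4 MC SEs
  expect_equal(colMeans(Y), mg$mean, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(stats::cov(Y), mg$cov, tolerance = 0.03, ignore_attr = TRUE)
})

test_that("log-likelihood equals the direct MVN density oracle", {
  set.seed(7)
  for (i in 1:10) {
    q <- sample(1:3, 1)
    lam <- rnorm(q); mu <- rnorm(q)
    m <- sem_model(lam, mu, runif(1, .1, 1), runif(1, .1, 1),
                   runif(1, .1, .5), runif(1, .1, .5))
    n <- 6
    X <- cbind(1, matrix(rnorm(n * (q - 1)), n))
    sim <- sem_simulate(m, X, 2, 3)
    obs <- sem_observations(X, sim$p, sim$r)
    ll <- sem_loglik(m, obs)
    direct <- sum(vapply(seq_len(n), function(i) {
      mg <- sem_marginal(m, X[i, ], 2, 3)
      dmvnorm_log(c(sim$p[i, ], sim$r[i, ]), mg$mean, mg$cov)
    }, numeric(1)))
    expect_equal(ll, direct, tolerance = 1e-10)
  }
})

test_that("log-likelihood is additive and row-permutation invariant", {
  set.seed(9)
  m <- sem_model(c(0, 1), c(1, -1), 0.5, 0.5, 0.3, 0.3)
  X <- cbind(1, rnorm(8))
  sim <- sem_simulate(m, X, 2, 2)
  obs <- sem_observations(X, sim$p, sim$r)
  perm <- sample(8)
  obs_perm <- sem_observations(X[perm, ], sim$p[perm, ], sim$r[perm, ])
  expect_equal(sem_loglik(m, obs), sem_loglik(m, obs_perm))
  half1 <- sem_observations(X[1:4, ], sim$p[1:4, ], sim$r[1:4, ])
  half2 <- sem_observations(X[5:8, ], sim$p[5:8, ], sim$r[5:8, ])
  expect_equal(sem_loglik(m, obs),
               sem_loglik(m, half1) + sem_loglik(m, half2))
})

test_that("observation validation rejects malformed inputs", {
  X <- cbind(1, rnorm(3))
  p <- matrix(rnorm(6), 3); r <- matrix(rnorm(6), 3)
  expect_error(sem_observations(X[, 2:1], p, r), "intercept")
  pbad <- p; pbad[1, 1] <- Inf
  expect_error(sem_observations(X, pbad, r), "non-finite")
  pna <- p; pna[1, ] <- NA; rna <- r; rna[1, ] <- NA
  expect_error(sem_observations(X, pna, rna), "no finite")
  # a single missing replicate is allowed
  expect_s3_class(sem_observations(X, pna, r), "sem_observations")
})

test_that("fit recovers known coefficients within 3 SEs on a moderate panel", {
  set.seed(100)
  lam <- c(2, 0.5, -0.3); mu <- c(1, 0, 0.4)
  m <- sem_model(lam, mu, 0.5, 0.4, 0.2, 0.2)
  n <- 1200
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(intercept)", "f1", "f2")
  sim <- sem_simulate(m, X, 2, 2)
  fit <- sem_fit(sem_observations(X, sim$p, sim$r), standardize = FALSE)
  expect_true(fit$converged)
  expect_true(all(abs(fit$lambda - lam) <= 3 * fit$se_lambda))
  expect_true(all(abs(fit$mu - mu) <= 3 * fit$se_mu))
  sg <- c(fit$model$sigma_b, fit$model$sigma_t,
          fit$model$sigma_p, fit$model$sigma_r)
  expect_equal(sg, c(0.5, 0.4, 0.2, 0.2), tolerance = 0.15)
  # the truly null coefficient (mu for f1) should not earn 3 stars
  tab <- sem_fit_table(fit)
  expect_equal(tab$feature, colnames(X))
  expect_false(tab$stars_mu[2] == "***")
  # strong coefficients are significant
  expect_equal(tab$stars_lambda[1], "***")
})

test_that("profiled estimate maximizes: GLS beats coefficient perturbations", {
  set.seed(17)
  m <- sem_model(c(1, 0.3), c(0.5, -0.2), 0.4, 0.3, 0.2, 0.2)
  n <- 300
  X <- cbind(1, rnorm(n))
  sim <- sem_simulate(m, X, 2, 2)
  obs <- sem_observations(X, sim$p, sim$r)
  fit <- sem_fit(obs, standardize = FALSE)
  ll_hat <- sem_loglik(fit$model, obs)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  for (i in 1:10) {
    pert <- fit$model
    pert$lambda <- pert$lambda + rnorm(2, 0, 0.05)
    pert$mu <- pert$mu + rnorm(2, 0, 0.05)
    expect_lt(sem_loglik(pert, obs), ll_hat + 1e-8)
  }
})

test_that("standardization changes slope scale but not inference or fit", {
  set.seed(23)
  m <- sem_model(c(1, 0.02), c(0.5, -0.01), 0.4, 0.3, 0.2, 0.2)
  n <- 500
  X <- cbind(1, rnorm(n, 0, 25))  # wide-scale feature
  colnames(X) <- c("(intercept)", "big")
  sim <- sem_simulate(m, X, 2, 2)
  obs <- sem_observations(X, sim$p, sim$r)
  f_raw <- sem_fit(obs, standardize = FALSE)
  f_std <- sem_fit(obs, standardize = TRUE)
  expect_equal(f_std$loglik, f_raw$loglik, tolerance = 1e-4)
  # slope back-transform: beta_raw = beta_std / scale
  expect_equal(f_std$lambda[2] / f_std$scales[2], f_raw$lambda[2],
               tolerance = 1e-3)
  expect_equal(f_std$z_lambda[2], f_raw$z_lambda[2], tolerance = 1e-2)
  # log2 reporting divides estimates and SEs by ln 2, Z unchanged
  f_l2 <- sem_fit(obs, standardize = FALSE, log2_report = TRUE)
  expect_equal(f_l2$lambda, f_raw$lambda / log(2), tolerance = 1e-6)
  expect_equal(f_l2$z_lambda, f_raw$z_lambda, tolerance = 1e-6)
})

test_that("missing replicates are handled by covariance-pattern grouping", {
  set.seed(29)
  m <- sem_model(c(1), c(0.5), 0.4, 0.3, 0.2, 0.2)
  n <- 800
  X <- matrix(1, n, 1)
  sim <- sem_simulate(m, X, 2, 2)
  p <- sim$p
  p[sample(n, 200), 2] <- NA  # a quarter lose one PRO replicate
  obs <- sem_observations(X, p, sim$r)
  fit <- sem_fit(obs, standardize = FALSE)
  expect_true(abs(fit$lambda[1] - 1) <= 3 * fit$se_lambda[1])
  expect_true(abs(fit$mu[1] - 0.5) <= 3 * fit$se_mu[1])
  # the loglik of a complete-data model evaluated on obs must be finite
  expect_true(is.finite(sem_loglik(fit$model, obs)))
})

test_that("singular feature matrices are rejected with the column named", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  colnames(X) <- c("(intercept)", "a", "dup")
  p <- matrix(rnorm(8), 4); r <- matrix(rnorm(8), 4)
  obs <- sem_observations(X, p, r)
  expect_error(sem_fit(obs), "dup")
})
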