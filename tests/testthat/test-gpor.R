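test_that("ARD kernel values, symmetry and positive definiteness", {
  expect_equal(ard_kernel(rbind(c(0, 0)), rbind(c(1, 1)), c(1, 1))[1, 1],
               exp(-1), tolerance = 1e-12)
  X <- matrix(rnorm(20), ncol = 2)
  expect_equal(diag(ard_kernel(X, X, c(0.7, 2))), rep(1, 10))
  expect_equal(ard_kernel(X, X, c(0, 0)), matrix(1, 10, 10))
  K <- ard_kernel(X, X, c(0.7, 2))
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_gt(min(eigen(K + diag(1e-6, 10), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_error(ard_kernel(X, matrix(0, 2, 3), c(1, 1)), "dimension")
})

test_that("ordinal label probabilities are a proper, stable distribution", {
  hy <- quick_hyper()
  f <- c(-30, -3, 0, 1.2, 30)
  P <- ordinal_label_probs(f, hy)
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-12)
  expect_true(all(P > 0))
  # direct normal-CDF oracle: f = 0, b = (-1, 1), sigma = 1, R = 3
  hy3 <- gpor_hyper(1, 1, c(-1, 1))
  expect_equal(ordinal_label_probs(0, hy3)[1, 2], pnorm(1) - pnorm(-1),
               tolerance = 1e-12)
  # sigma -> 0 recovers the ideal noise-free likelihood
  hy_small <- gpor_hyper(1, 1e-6, c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(ordinal_label_probs(0, hy_small)[1, 3], 1, tolerance = 1e-9)
  # logs survive |z| >> 8
  expect_true(all(is.finite(log(ordinal_label_probs(c(-50, 50), hy)))))
})

test_that("MAP at N = 1 matches a brute-force grid search", {
  hy <- quick_hyper(D = 1)
  for (y in c(1L, 3L, 5L)) {
    d <- ordinal_data(matrix(0.3, 1, 1), y, 5L)
    fit <- map_estimate(d, hy)
    fgrid <- seq(-5, 5, by = 0.001)
    obj <- log(ordinal_label_probs(fgrid, hy))[cbind(seq_along(fgrid), y)] -
      0.5 * fgrid^2 / (1 + 1e-6)  # prior variance includes the jitter
    expect_equal(fit$f_map, fgrid[which.max(obj)], tolerance = 2e-3)
    expect_true(fit$converged)
  }
})

test_that("MAP respects label-mirror symmetry and increases monotonically", {
  set.seed(81)
  X <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  y <- c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L)
  hy <- quick_hyper(D = 1)  # thresholds symmetric about 0
  f1 <- map_estimate(ordinal_data(X, y, 5L), hy)
  # mirrored inputs and reversed labels flip the sign of the MAP
  f2 <- map_estimate(ordinal_data(-X, 6L - y, 5L), hy)
  expect_equal(f2$f_map, -f1$f_map, tolerance = 1e-6)
  # Newton iterates monotonically increase the objective
  expect_true(all(diff(f1$objective_trace) >= -1e-12))
  # stationarity: gradient of the log posterior vanishes at the mode
  terms <- faceutility:::ordinal_loglik_terms(f1$f_map, y, hy)
  expect_lt(max(abs(terms$d1 - f1$alpha)), 1e-6)
  # empty dataset reduces to the prior
  f0 <- map_estimate(ordinal_data(matrix(0, 0, 1), integer(), 5L), hy)
  expect_length(f0$f_map, 0)
})

test_that("Laplace evidence matches dense quadrature at N = 1 and N = 2", {
  hy <- quick_hyper(D = 1)
  jit <- 1e-6
  d1 <- ordinal_data(matrix(0.2, 1, 1), 4L, 5L)
  ev1 <- log_evidence(d1, hy)
  q1 <- integrate(function(f) {
    ordinal_label_probs(f, hy)[, 4] * dnorm(f, 0, sqrt(1 + jit))
  }, -10, 10, rel.tol = 1e-10)$value
  expect_lt(abs(ev1 - log(q1)), 0.02)
  expect_lte(ev1, 0)

  d2 <- ordinal_data(matrix(c(-0.5, 0.8), 2, 1), c(2L, 4L), 5L)
  ev2 <- log_evidence(d2, hy)
  K <- ard_kernel(d2$x, d2$x, hy$eta) + diag(jit, 2)
  gr <- seq(-6, 6, length.out = 401)
  h <- gr[2] - gr[1]
  Kinv <- solve(K)
  dens <- outer(gr, gr, function(a, b) {
    quad <- Kinv[1, 1] * a^2 + 2 * Kinv[1, 2] * a * b + Kinv[2, 2] * b^2
    exp(-0.5 * quad) / (2 * pi * sqrt(det(K)))
  })
  lik <- outer(gr, gr, function(a, b) {
    ordinal_label_probs(a, hy)[, 2] * ordinal_label_probs(b, hy)[, 4]
  })
  q2 <- sum(dens * lik) * h^2
  expect_lt(abs(ev2 - log(q2)), 0.05)
})

test_that("latent predictions satisfy the Laplace identities", {
  d <- toy_dataset(N = 25, seed = 3)
  hy <- quick_hyper(D = 1)
  m <- fit_gpor(d, hy)
  # at a training point the mean reproduces the MAP value
  pr <- predict_latent(m, d$x[7, , drop = FALSE])
  expect_equal(pr$mu, m$f_map[7], tolerance = 1e-4)
  # far from all data: prior moments
  far <- predict_latent(m, matrix(1e4, 1, 1))
  expect_equal(far$mu, 0, tolerance = 1e-10)
  expect_equal(far$var, 1, tolerance = 1e-10)
  # posterior variance never exceeds the prior variance
  g <- matrix(seq(-2, 2, by = 0.1), ncol = 1)
  expect_true(all(predict_latent(m, g)$var <= 1 + 1e-8))
})

test_that("latent predictions match Monte-Carlo moments of the Laplace posterior", {
  set.seed(91)
  d <- toy_dataset(N = 3, seed = 5)
  hy <- quick_hyper(D = 1)
  m <- fit_gpor(d, hy)
  xs <- matrix(seq(-2, 2, length.out = 10), ncol = 1)
  pr <- predict_latent(m, xs)
  # sample f from the Laplace posterior, then f* from the GP conditional
  n_mc <- 200000L
  K <- m$K
  Sigma <- solve(solve(K) + diag(m$lambda_map))
  Us <- chol(Sigma)
  F <- matrix(rnorm(n_mc * 3), n_mc, 3) %*% Us +
    matrix(m$f_map, n_mc, 3, byrow = TRUE)
  Ks <- ard_kernel(d$x, xs, hy$eta)
  A <- solve(K, Ks)                      # N x m
  cond_mu <- F %*% A                     # n_mc x m
  cond_var <- pmax(1 - colSums(Ks * A), 0)
  fstar <- cond_mu + matrix(rnorm(n_mc * 10), n_mc, 10) %*% diag(sqrt(cond_var))
  mc_mu <- colMeans(fstar)
  mc_var <- apply(fstar, 2, var)
  se_mu <- apply(fstar, 2, sd) / sqrt(n_mc)
  expect_true(all(abs(mc_mu - pr$mu) < 4 * se_mu))
  expect_true(all(abs(mc_var - pr$var) / pr$var < 0.03))
})

test_that("label predictions integrate the likelihood correctly", {
  d <- toy_dataset(N = 20, seed = 7)
  hy <- quick_hyper(D = 1)
  m <- fit_gpor(d, hy)
  xs <- matrix(c(-1.5, 0, 1.2), ncol = 1)
  pl <- predict_labels(m, xs)
  expect_equal(rowSums(pl$probs), rep(1, 3), tolerance = 1e-12)
  # Monte-Carlo check of the closed form at one point
  pr <- predict_latent(m, xs[2, , drop = FALSE])
  set.seed(17)
  n_mc <- 100000L
  fdraw <- rnorm(n_mc, pr$mu, sqrt(pr$var))
  ydraw <- findInterval(fdraw + rnorm(n_mc, 0, hy$sigma), hy$b) + 1L
  freq <- tabulate(ydraw, 5) / n_mc
  se <- sqrt(pmax(freq * (1 - freq), 1e-6) / n_mc)
  expect_true(all(abs(freq - pl$probs[2, ]) < 4 * se))
  # zero predictive variance reduces to the plain ordinal likelihood:
  # a model with no data queried through ordinal_label_probs at mu
  s <- sqrt(hy$sigma^2 + pr$var)
  hy_s <- gpor_hyper(hy$eta, s, hy$b)
  expect_equal(predict_labels(m, xs[2, , drop = FALSE])$probs[1, ],
               ordinal_label_probs(pr$mu, hy_s)[1, ], tolerance = 1e-10)
})

test_that("hyperparameter fitting is reproducible and near-optimal", {
  d <- toy_dataset(N = 60, D = 1, seed = 9)
  h1 <- fit_hyperparams(d, n_restarts = 2, seed = 5, maxit = 150)
  h2 <- fit_hyperparams(d, n_restarts = 2, seed = 5, maxit = 150)
  expect_identical(h1, h2)  # bit-identical under a fixed seed

  # evidence at the fitted hyperparameters beats the generating ones
  true_hy <- gpor_hyper(0.5, 1, c(-1.5, -0.5, 0.5, 1.5))
  expect_gte(attr(h1, "log_evidence"), log_evidence(d, true_hy) - 0.1)
})

test_that("likelihood is translation invariant; fitted evidence is stable", {
  # the exact identity behind 'monotone relabeling': shifting both the
  # latent values and the thresholds by a constant leaves the likelihood
  # unchanged (the evidence itself is not invariant: the prior is zero-mean)
  hy <- quick_hyper(D = 1)
  f <- c(-1.2, 0.3, 2.1)
  y <- c(1L, 3L, 5L)
  shift <- 0.9
  hy_s <- gpor_hyper(hy$eta, hy$sigma, hy$b + shift)
  t1 <- faceutility:::ordinal_loglik_terms(f, y, hy)
  t2 <- faceutility:::ordinal_loglik_terms(f + shift, y, hy_s)
  expect_equal(t1$logp, t2$logp, tolerance = 1e-12)

  # starting the optimizer from shifted thresholds lands on the same optimum
  d <- toy_dataset(N = 40, D = 1, seed = 11)
  h_a <- fit_hyperparams(d, n_restarts = 1, seed = 2, maxit = 400)
  init <- gpor_hyper(h_a$eta, h_a$sigma, h_a$b + 0.5)
  h_b <- fit_hyperparams(d, init = init, n_restarts = 1, seed = 2,
                         maxit = 400)
  expect_lt(abs(attr(h_a, "log_evidence") - attr(h_b, "log_evidence")), 0.05)
})
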