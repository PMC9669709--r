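# Shared fixtures: tiny shapes, canonical hyperparameters and simulated
# datasets built in code (no stored data files).

toy_triangle <- function() matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)

rot2 <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2,
         byrow = TRUE)
}

# canonical 5-category hyperparameters used across gpor tests
quick_hyper <- function(D = 1L, eta = 0.5, sigma = 1) {
  gpor_hyper(eta = rep(eta, D), sigma = sigma, b = c(-1.5, -0.5, 0.5, 1.5))
}

# small simulated rating dataset from the package's own generative model
toy_dataset <- function(N = 30L, D = 1L, seed = 1L, peak = rep(0.5, D),
                        sigma = 1) {
  u <- true_utility("quadratic_peak", D = D, peak = peak, curvature = 0.5,
                    amplitude = 2)
  p <- sim_participant(u, noise_sd = sigma, seed = seed)
  X <- faceutility:::with_seed(seed + 100L,
                               matrix(runif(N * D, -2, 2), ncol = D))
  ordinal_data(X, simulate_response(p, X), 5L)
}

# independent iterated grid-search maximizer of the cumulative-logit
# likelihood (oracle for fit_ordinal_logistic); final resolution <= 0.01
ologit_grid_oracle <- function(x, y, R) {
  nll <- function(beta, zeta) {
    zfull <- c(-Inf, zeta, Inf)
    lin <- as.vector(x %*% beta)
    p <- plogis(zfull[y + 1L] - lin) - plogis(zfull[y] - lin)
    -sum(log(pmax(p, 1e-300)))
  }
  stopifnot(ncol(x) == 1L, R == 3L)  # oracle specialized to D = 1, R = 3
  best <- c(0, -1, 1); width <- 4
  repeat {
    bs <- seq(best[1] - width, best[1] + width, length.out = 17)
    z1s <- seq(best[2] - width, best[2] + width, length.out = 17)
    z2s <- seq(best[3] - width, best[3] + width, length.out = 17)
    val <- Inf
    for (b in bs) for (z1 in z1s) for (z2 in z2s) {
      if (z2 <= z1) next
      v <- nll(b, c(z1, z2))
      if (v < val) { val <- v; cand <- c(b, z1, z2) }
    }
    best <- cand
    width <- width / 4
    if (width < 0.005) break
  }
  list(par = best, loglik = -val)
}
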