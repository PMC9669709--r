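## Gaussian process ordinal regression (GPOR) with Laplace inference.
##
## Model: a zero-mean GP prior f ~ GP(0, K) with an RBF ARD kernel, observed
## through an ordinal likelihood: the latent utility is contaminated with
## Gaussian noise (SD sigma) and cut at ordered thresholds b_1 < ... <
## b_{R-1}, so P(y | f) = Phi((b_y - f)/sigma) - Phi((b_{y-1} - f)/sigma).
## Inference uses the Laplace approximation at the MAP latent vector; the
## likelihood is log-concave in f, so Newton iterations from f = 0 converge
## to the unique posterior mode.

#' Ordinal rating dataset
#'
#' @param x N x D matrix of stimulus coordinates (PC scores in SD units).
#' @param y integer vector of N ordinal labels in 1..R.
#' @param R number of ordinal categories.
#' @return an object of class `ordinal_data`.
#' @export
ordinal_data <- function(x, y, R = 5L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  R <- as.integer(R)
  if (nrow(x) != length(y)) stop("|x| and |y| must match")
  if (length(y) && (any(y < 1L) || any(y > R))) {
    stop("labels must lie in 1..", R)
  }
  if (!all(is.finite(x))) stop("stimulus coordinates must be finite")
  structure(list(x = x, y = y, R = R, N = length(y), D = ncol(x)),
            class = "ordinal_data")
}

#' GPOR hyperparameters
#'
#' @param eta nonnegative ARD weights, one inverse-squared-length-scale per
#'   input dimension.
#' @param sigma ordinal noise standard deviation (> 0).
#' @param b strictly increasing vector of R-1 finite thresholds; the outer
#'   thresholds b_0 = -Inf and b_R = +Inf are implicit.
#' @return an object of class `gpor_hyper`.
#' @export
gpor_hyper <- function(eta, sigma, b) {
  eta <- as.numeric(eta); sigma <- as.numeric(sigma); b <- as.numeric(b)
  if (any(eta < 0)) stop("eta must be nonnegative")
  if (sigma <= 0) stop("sigma must be positive")
  if (length(b) < 1L || any(diff(b) <= 0)) {
    stop("thresholds b must be strictly increasing")
  }
  structure(list(eta = eta, sigma = sigma, b = b, R = length(b) + 1L),
            class = "gpor_hyper")
}

#' RBF kernel with automatic relevance determination
#'
#' `K(x, x') = exp(-1/2 * sum_d eta_d (x_d - x'_d)^2)`.
#'
#' @param X1,X2 matrices of coordinates (rows = points, columns =
#'   dimensions) with matching dimension.
#' @param eta nonnegative ARD weights, one per dimension.
#' @return the `nrow(X1)` x `nrow(X2)` kernel matrix.
#' @export
ard_kernel <- function(X1, X2, eta) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("dimension mismatch between X1 and X2")
  if (length(eta) == 1L) eta <- rep(eta, ncol(X1))
  if (length(eta) != ncol(X1)) stop("eta must have one weight per dimension")
  if (any(eta < 0)) stop("eta must be nonnegative")
  S1 <- sweep(X1, 2, sqrt(eta), "*")
  S2 <- sweep(X2, 2, sqrt(eta), "*")
  d2 <- outer(rowSums(S1^2), rowSums(S2^2), "+") - 2 * tcrossprod(S1, S2)
  d2[d2 < 0] <- 0
  exp(-0.5 * d2)
}

# Numerically stable Phi(z1) - Phi(z0) for z1 >= z0 (uses the complementary
# tail when both arguments are positive), floored at 1e-300.
pnorm_interval <- function(z0, z1) {
  p <- ifelse(z0 > 0,
              pnorm(z0, lower.tail = FALSE) - pnorm(z1, lower.tail = FALSE),
              pnorm(z1) - pnorm(z0))
  pmax(p, 1e-300)
}

zphi <- function(z) ifelse(is.finite(z), z * dnorm(z), 0)
phi0 <- function(z) ifelse(is.finite(z), dnorm(z), 0)

# Log-likelihood, first and second derivatives w.r.t. f, per observation.
ordinal_loglik_terms <- function(f, y, hyper) {
  bfull <- c(-Inf, hyper$b, Inf)
  z1 <- (bfull[y + 1L] - f) / hyper$sigma
  z0 <- (bfull[y] - f) / hyper$sigma
  p <- pnorm_interval(z0, z1)
  d1 <- -(phi0(z1) - phi0(z0)) / (hyper$sigma * p)
  d2 <- -(zphi(z1) - zphi(z0)) / (hyper$sigma^2 * p) - d1^2
  list(logp = log(p), d1 = d1, d2 = d2)
}

#' Ordinal label probabilities at a latent value
#'
#' `P(y | f) = Phi((b_y - f)/sigma) - Phi((b_{y-1} - f)/sigma)`, computed
#' with tail-stable normal CDF differences.
#'
#' @param f numeric vector of latent utility values.
#' @param hyper a [gpor_hyper()] object.
#' @return a `length(f)` x R matrix of probabilities; rows sum to 1.
#' @export
ordinal_label_probs <- function(f, hyper) {
  bfull <- c(-Inf, hyper$b, Inf)
  R <- hyper$R
  out <- vapply(seq_len(R), function(s) {
    pnorm_interval((bfull[s] - f) / hyper$sigma,
                   (bfull[s + 1L] - f) / hyper$sigma)
  }, numeric(length(f)))
  out <- matrix(out, ncol = R)
  out / rowSums(out)
}

# Cholesky of K with escalating diagonal jitter (1e-6 * 10^k up to 1e-2).
chol_with_jitter <- function(K, start = 1e-6, max_jitter = 1e-2) {
  jit <- start
  repeat {
    U <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jit))
    jit <- jit * 10
    if (jit > max_jitter) stop("kernel matrix not positive definite even ",
                               "with jitter ", max_jitter)
  }
}

#' MAP estimate of the latent utility vector
#'
#' Newton-Raphson maximization of the log posterior
#' `sum_i log P(y_i | f_i) - f' K^{-1} f / 2` starting from `f = 0`, in the
#' numerically stable parameterization that avoids forming `K^{-1}`
#' explicitly.  Step halving enforces a monotone increase of the objective;
#' iteration stops when the gradient infinity-norm drops below `tol`.
#'
#' @param data an [ordinal_data()] object.
#' @param hyper a [gpor_hyper()] object with `length(eta) == ncol(data$x)`.
#' @param tol gradient infinity-norm tolerance.
#' @param max_iter maximum Newton iterations.
#' @return a list with `f_map`, `lambda_map` (diagonal of the negative
#'   likelihood Hessian at the mode), `alpha` (`K^{-1} f_map`), the jittered
#'   kernel factor, the Laplace `log_evidence`, and convergence info.
#' @export
map_estimate <- function(data, hyper, tol = 1e-6, max_iter = 100L) {
  N <- data$N
  if (hyper$R != data$R) stop("hyper and data disagree on R")
  if (N == 0L) {
    return(list(f_map = numeric(0), lambda_map = numeric(0),
                alpha = numeric(0), K = matrix(0, 0, 0), jitter = 0,
                sW = numeric(0), L = matrix(0, 0, 0),
                log_evidence = 0, iterations = 0L, converged = TRUE,
                objective = 0))
  }
  K0 <- ard_kernel(data$x, data$x, hyper$eta)
  cj <- chol_with_jitter(K0)
  K <- K0 + diag(cj$jitter, N)

  f <- numeric(N); alpha <- numeric(N)
  terms <- ordinal_loglik_terms(f, data$y, hyper)
  obj <- sum(terms$logp)
  trace_obj <- obj
  converged <- FALSE
  iter <- 0L
  sW <- numeric(N); L <- diag(1, N)
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- pmax(-terms$d2, 0)
    sW <- sqrt(W)
    B <- diag(1, N) + (sW %o% sW) * K
    L <- chol(B)  # upper triangular: B = t(L) %*% L
    bvec <- W * f + terms$d1
    v <- forwardsolve(t(L), sW * as.vector(K %*% bvec))
    alpha_new <- bvec - sW * backsolve(L, v)
    # line search in alpha-space so the quadratic term stays exact
    step <- 1
    repeat {
      a_try <- alpha + step * (alpha_new - alpha)
      f_try <- as.vector(K %*% a_try)
      t_try <- ordinal_loglik_terms(f_try, data$y, hyper)
      obj_try <- sum(t_try$logp) - 0.5 * sum(a_try * f_try)
      if (obj_try >= obj || step < 1e-8) break
      step <- step / 2
    }
    alpha <- a_try; f <- f_try; terms <- t_try; obj <- obj_try
    trace_obj <- c(trace_obj, obj)
    grad <- terms$d1 - alpha
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("MAP Newton iteration failed to converge in ", max_iter,
         " iterations (objective trace: ",
         paste(format(utils::tail(trace_obj, 5), digits = 8), collapse = ", "),
         ")")
  }
  W <- pmax(-terms$d2, 0)
  sW <- sqrt(W)
  L <- chol(diag(1, N) + (sW %o% sW) * K)
  log_evidence <- obj - sum(log(diag(L)))
  list(f_map = f, lambda_map = W, alpha = alpha, K = K, jitter = cj$jitter,
       sW = sW, L = L, log_evidence = log_evidence, iterations = iter,
       converged = converged, objective = obj, objective_trace = trace_obj)
}

#' Fit a GPOR model at fixed hyperparameters
#'
#' Runs [map_estimate()] and packages the result with the data and
#' hyperparameters for prediction.
#'
#' @inheritParams map_estimate
#' @return an object of class `gpor_model`.
#' @export
fit_gpor <- function(data, hyper, tol = 1e-6, max_iter = 100L) {
  fit <- map_estimate(data, hyper, tol = tol, max_iter = max_iter)
  structure(c(list(data = data, hyper = hyper), fit), class = "gpor_model")
}

#' @export
print.gpor_model <- function(x, ...) {
  cat("GPOR model: N =", x$data$N, " D =", x$data$D, " R =", x$data$R, "\n")
  cat("  eta =", format(x$hyper$eta, digits = 4),
      " sigma =", format(x$hyper$sigma, digits = 4), "\n")
  cat("  b =", format(x$hyper$b, digits = 4), "\n")
  cat("  Laplace log evidence =", format(x$log_evidence, digits = 6), "\n")
  invisible(x)
}

#' Laplace approximation to the log model evidence
#'
#' `log P(D) ~ log lik at MAP - f' K^{-1} f / 2 - log det(I + K Lambda) / 2`.
#'
#' @inheritParams map_estimate
#' @return a scalar (<= 0 up to Laplace error: it approximates the log
#'   probability of the discrete labels).
#' @export
log_evidence <- function(data, hyper, tol = 1e-6, max_iter = 100L) {
  map_estimate(data, hyper, tol = tol, max_iter = max_iter)$log_evidence
}

# Pack/unpack the unconstrained hyperparameter vector used by the optimizer:
# (log eta_1..D, log sigma, b_1, log diff(b)_2..R-1).
hyper_to_theta <- function(hyper) {
  c(log(pmax(hyper$eta, 1e-12)), log(hyper$sigma), hyper$b[1],
    if (hyper$R > 2L) log(diff(hyper$b)))
}

theta_to_hyper <- function(theta, D, R) {
  eta <- exp(theta[seq_len(D)])
  sigma <- exp(theta[D + 1L])
  b1 <- theta[D + 2L]
  b <- if (R > 2L) b1 + c(0, cumsum(exp(theta[D + 2L + seq_len(R - 2L)]))) else b1
  gpor_hyper(eta, sigma, b)
}

# Heuristic starting hyperparameters: moderate length scales relative to the
# input spread, unit noise, thresholds at the normal quantiles of the
# empirical cumulative label frequencies.
default_hyper_init <- function(data) {
  D <- data$D; R <- data$R
  spread <- apply(data$x, 2, stats::sd)
  spread[!is.finite(spread) | spread < 0.1] <- 1
  eta <- 1 / (spread^2)
  freq <- tabulate(data$y, nbins = R)
  cum <- cumsum(freq)[-R] / max(sum(freq), 1)
  cum <- pmin(pmax(cum, 0.02), 0.98)
  b <- qnorm(cum)
  b <- cummax(b + seq(0, 1e-3, length.out = R - 1L))  # enforce strict order
  if (any(diff(b) <= 0)) b <- seq(-1.5, 1.5, length.out = R - 1L)
  gpor_hyper(eta, 1, b)
}

#' Select GPOR hyperparameters by Laplace evidence maximization
#'
#' Maximizes the Laplace approximation to the log evidence over
#' `(log eta, log sigma, b_1, log increments of b)` by Nelder-Mead from
#' `n_restarts` starting points: the data-driven heuristic start plus
#' seeded random perturbations of it.
#'
#' @param data an [ordinal_data()] object.
#' @param init optional [gpor_hyper()] used as the first start.
#' @param n_restarts number of optimizer starts.
#' @param seed integer seed controlling the restart perturbations; with a
#'   fixed seed the result is fully reproducible.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @return the best [gpor_hyper()] found, with attributes `log_evidence`
#'   and `n_fail` (starts that errored).
#' @export
fit_hyperparams <- function(data, init = NULL, n_restarts = 5L, seed = 1L,
                            maxit = 300L) {
  if (data$N < 2L) stop("need at least two observations to fit hyperparameters")
  D <- data$D; R <- data$R
  init <- init %||% default_hyper_init(data)
  theta0 <- hyper_to_theta(init)
  neg_evidence <- function(theta) {
    hy <- tryCatch(theta_to_hyper(theta, D, R), error = function(e) NULL)
    if (is.null(hy)) return(1e10)
    ev <- tryCatch(log_evidence(data, hy), error = function(e) NA_real_)
    if (!is.finite(ev)) 1e10 else -ev
  }
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(k) {
      if (k == 1L) theta0 else theta0 + rnorm(length(theta0), sd = 0.6)
    })
  })
  best <- NULL; n_fail <- 0L
  for (th in starts) {
    res <- tryCatch(
      stats::optim(th, neg_evidence, method = "Nelder-Mead",
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) {
      n_fail <- n_fail + 1L
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("hyperparameter fitting failed in all ", n_restarts, " restarts")
  }
  out <- theta_to_hyper(best$par, D, R)
  attr(out, "log_evidence") <- -best$value
  attr(out, "n_fail") <- n_fail
  out
}

#' Laplace predictive distribution of the latent utility
#'
#' Mean `k*' K^{-1} f_MAP` and variance
#' `K(x*, x*) - k*' (K + Lambda^{-1})^{-1} k*`, the latter evaluated through
#' the symmetric form with `Lambda^{1/2}` so near-zero curvature entries
#' never get inverted.
#'
#' @param model a fitted [fit_gpor()] model.
#' @param x_star an m x D matrix (or length-D vector) of query coordinates.
#' @return a data.frame with columns `mu` and `var` (variance clamped at 0;
#'   a warning is raised if the pre-clamp deficit exceeds 1e-8).
#' @export
predict_latent <- function(model, x_star) {
  if (!inherits(model, "gpor_model")) stop("`model` must be a gpor_model")
  X <- if (is.null(dim(x_star))) matrix(x_star, nrow = 1) else as.matrix(x_star)
  if (model$data$N == 0L) {
    return(data.frame(mu = rep(0, nrow(X)), var = rep(1, nrow(X))))
  }
  if (ncol(X) != model$data$D) stop("x_star dimension mismatch")
  Ks <- ard_kernel(model$data$x, X, model$hyper$eta)     # N x m
  mu <- as.vector(crossprod(Ks, model$alpha))
  v <- forwardsolve(t(model$L), model$sW * Ks)           # N x m
  var <- 1 - colSums(v^2)
  if (any(var < -1e-8)) {
    warning("predictive variance clamped from ", min(var), " to 0")
  }
  data.frame(mu = mu, var = pmax(var, 0))
}

#' Predictive label distribution and point prediction
#'
#' Integrates the ordinal likelihood over the Gaussian latent predictive in
#' closed form: `P(y = s | x*) = Phi((b_s - mu)/s*) - Phi((b_{s-1} - mu)/s*)`
#' with `s* = sqrt(sigma^2 + var_x*)`.  The point prediction is the modal
#' label; ties resolve to the smaller label.
#'
#' @param model a fitted [fit_gpor()] model.
#' @param x_star query coordinates (m x D matrix or length-D vector).
#' @return a list with `probs` (m x R matrix) and `yhat` (integer vector).
#' @export
predict_labels <- function(model, x_star) {
  pl <- predict_latent(model, x_star)
  s <- sqrt(model$hyper$sigma^2 + pl$var)
  bfull <- c(-Inf, model$hyper$b, Inf)
  R <- model$hyper$R
  probs <- vapply(seq_len(R), function(k) {
    pnorm_interval((bfull[k] - pl$mu) / s, (bfull[k + 1L] - pl$mu) / s)
  }, numeric(nrow(pl)))
  probs <- matrix(probs, ncol = R)
  probs <- probs / rowSums(probs)
  list(probs = probs, yhat = as.integer(apply(probs, 1, which.max)))
}
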