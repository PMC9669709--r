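## LOOCV benchmarking: proportional-odds ordinal logistic regression as the
## linear baseline, mean zero-one error (MZE) and mean absolute error (MAE)
## as the ordinal loss functions, and paired comparisons across raters.

plogis_interval <- function(z0, z1) {
  p <- ifelse(z0 > 0,
              plogis(z0, lower.tail = FALSE) - plogis(z1, lower.tail = FALSE),
              plogis(z1) - plogis(z0))
  pmax(p, 1e-300)
}

ologit_negloglik <- function(theta, x, y, R, ridge = 0) {
  D <- ncol(x)
  beta <- theta[seq_len(D)]
  z1 <- theta[D + 1L]
  zeta <- if (R > 2L) z1 + c(0, cumsum(exp(theta[D + 1L + seq_len(R - 2L)]))) else z1
  zfull <- c(-Inf, zeta, Inf)
  lin <- if (D > 0L) as.vector(x %*% beta) else numeric(length(y))
  ll <- sum(log(plogis_interval(zfull[y] - lin, zfull[y + 1L] - lin)))
  -ll + ridge * sum(theta^2)
}

#' Fit a proportional-odds ordinal logistic regression
#'
#' Cumulative-link logit model `logit P(y <= s | x) = zeta_s - x'beta`,
#' maximum likelihood by BFGS with cutpoints parameterized as
#' `zeta_1` plus log-increments so monotonicity is enforced.  Apparent
#' complete separation (diverging coefficients or optimizer failure) is
#' flagged and refit with a small ridge penalty (1e-4).
#'
#' @param data an [ordinal_data()] object with at least two distinct labels.
#' @return an object of class `ordinal_logit` with `beta`, `zeta`
#'   (cutpoints), `loglik` and `converged`.
#' @export
fit_ordinal_logistic <- function(data) {
  x <- data$x; y <- data$y; R <- data$R; D <- data$D
  if (length(unique(y)) < 2L) stop("need at least two distinct labels")
  npar <- D + R - 1L
  freq <- tabulate(y, nbins = R)
  cum <- pmin(pmax(cumsum(freq)[-R] / sum(freq), 0.02), 0.98)
  z <- qlogis(cum)
  z <- z + cumsum(c(0, pmax(1e-3 - diff(z), 0)))  # strictly increasing start
  theta0 <- c(rep(0, D), z[1], if (R > 2L) log(diff(z)))
  run <- function(ridge) {
    stats::optim(theta0, ologit_negloglik, x = x, y = y, R = R, ridge = ridge,
                 method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  }
  fit <- tryCatch(run(0), error = function(e) NULL)
  # diverging coefficients signal separation: on SD-unit inputs |beta| > 15
  # corresponds to a per-SD odds ratio > 3e6, far outside plausible fits
  separated <- is.null(fit) || fit$convergence != 0 ||
    (D > 0L && max(abs(fit$par[seq_len(D)])) > 15) ||
    max(abs(fit$par)) > 50
  converged <- !separated
  if (separated) fit <- run(1e-4)
  theta <- fit$par
  beta <- theta[seq_len(D)]
  zeta <- if (R > 2L) {
    theta[D + 1L] + c(0, cumsum(exp(theta[D + 1L + seq_len(R - 2L)])))
  } else theta[D + 1L]
  structure(list(beta = beta, zeta = zeta, R = R, D = D,
                 loglik = -ologit_negloglik(theta, x, y, R),
                 converged = converged),
            class = "ordinal_logit")
}

#' Predicted label probabilities from an ordinal logistic model
#'
#' @param object a fitted [fit_ordinal_logistic()] model.
#' @param x_star query coordinates (m x D matrix or length-D vector).
#' @param ... unused.
#' @return a list with `probs` (m x R) and modal `yhat` (ties to the
#'   smaller label).
#' @export
predict.ordinal_logit <- function(object, x_star, ...) {
  X <- if (is.null(dim(x_star))) matrix(x_star, nrow = 1) else as.matrix(x_star)
  lin <- if (object$D > 0L) as.vector(X %*% object$beta) else numeric(nrow(X))
  zfull <- c(-Inf, object$zeta, Inf)
  probs <- vapply(seq_len(object$R), function(s) {
    plogis_interval(zfull[s] - lin, zfull[s + 1L] - lin)
  }, numeric(nrow(X)))
  probs <- matrix(probs, ncol = object$R)
  probs <- probs / rowSums(probs)
  list(probs = probs, yhat = as.integer(apply(probs, 1, which.max)))
}

#' Mean zero-one error and mean absolute error
#'
#' `MZE = mean(pred != truth)`; `MAE = mean(|pred - truth|)` treating the
#' ordinal labels as consecutive integers.
#'
#' @param pred,truth equal-length integer label vectors.
#' @return a named numeric vector `c(mze = ..., mae = ...)`.
#' @export
compute_mze_mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) == 0L) stop("need at least one prediction")
  c(mze = mean(pred != truth), mae = mean(abs(pred - truth)))
}

# Resolve a model family to fit/predict closures.
resolve_family <- function(model_family, refit_hyper, hyper, hyper_args) {
  if (is.list(model_family) && !is.null(model_family$fit)) return(model_family)
  switch(model_family,
    gpor = list(
      fit = function(d, fixed_hyper = NULL) {
        hy <- fixed_hyper %||% hyper
        if (is.null(hy)) {
          hy <- do.call(fit_hyperparams, c(list(d), hyper_args))
        }
        fit_gpor(d, hy)
      },
      predict = function(fit, x) predict_labels(fit, x)$yhat,
      hyper_of = function(fit) fit$hyper
    ),
    ologit = list(
      fit = function(d, fixed_hyper = NULL) fit_ordinal_logistic(d),
      predict = function(fit, x) predict(fit, x)$yhat,
      hyper_of = function(fit) NULL
    ),
    stop("unknown model family: ", model_family)
  )
}

#' Leave-one-out cross-validation of an ordinal prediction model
#'
#' For each trial the model is refit on the remaining N-1 trials and the
#' held-out label is predicted; test MZE/MAE are computed from the held-out
#' predictions and train MZE/MAE from the in-sample predictions of the
#' full-data fit.
#'
#' @param data an [ordinal_data()] object.
#' @param model_family `"gpor"`, `"ologit"`, or a list with `fit(data)` and
#'   `predict(fit, x)` entries.
#' @param refit_hyper for GPOR: `"per_fold"` refits hyperparameters in every
#'   fold (default, honest but slow); `"full_data"` reuses the full-data
#'   hyperparameters inside the folds (faster, mildly optimistic).
#' @param hyper optional fixed [gpor_hyper()] bypassing evidence
#'   maximization entirely.
#' @param hyper_args list of arguments forwarded to [fit_hyperparams()].
#' @return a list of class `loocv_report`: per-trial `pred_test`,
#'   `pred_train`, the error summary `errors` (mze/mae, test/train) and
#'   `n_failed` fold failures (excluded with a warning, never silent).
#' @export
loocv_evaluate <- function(data, model_family = "gpor",
                           refit_hyper = c("per_fold", "full_data"),
                           hyper = NULL, hyper_args = list()) {
  refit_hyper <- match.arg(refit_hyper)
  if (data$N < 2L) stop("LOOCV needs at least two trials")
  fam <- resolve_family(model_family, refit_hyper, hyper, hyper_args)
  full_fit <- fam$fit(data)
  fixed <- NULL
  if (identical(model_family, "gpor") && refit_hyper == "full_data" &&
      !is.null(fam$hyper_of)) {
    fixed <- fam$hyper_of(full_fit)
  }
  pred_train <- fam$predict(full_fit, data$x)
  pred_test <- rep(NA_integer_, data$N)
  n_failed <- 0L
  for (i in seq_len(data$N)) {
    d_i <- ordinal_data(data$x[-i, , drop = FALSE], data$y[-i], data$R)
    fit_i <- tryCatch(fam$fit(d_i, fixed_hyper = fixed),
                      error = function(e) NULL)
    if (is.null(fit_i)) {
      n_failed <- n_failed + 1L
      next
    }
    pred_test[i] <- fam$predict(fit_i, data$x[i, , drop = FALSE])
  }
  if (n_failed > 0L) {
    warning(n_failed, " LOOCV fold(s) failed to fit and were excluded")
  }
  ok <- !is.na(pred_test)
  if (!any(ok)) stop("all LOOCV folds failed")
  test <- compute_mze_mae(pred_test[ok], data$y[ok])
  train <- compute_mze_mae(pred_train, data$y)
  structure(list(
    pred_test = pred_test, pred_train = pred_train, n_failed = n_failed,
    errors = c(mze_test = unname(test["mze"]), mze_train = unname(train["mze"]),
               mae_test = unname(test["mae"]), mae_train = unname(train["mae"]))
  ), class = "loocv_report")
}

#' Paired comparison of per-rater error vectors
#'
#' Two-sided paired t-test and paired Cohen's d on per-rater errors of two
#' models evaluated on the same raters.
#'
#' @param errors_a,errors_b equal-length numeric vectors (one error per
#'   rater; same rater order).
#' @return a list with `t`, `df`, `p`, `d` (Cohen's d of the paired
#'   differences), `mean_diff` and a `degenerate` flag (zero-variance
#'   differences yield an infinite t).
#' @export
compare_models <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("unequal rater counts")
  n <- length(errors_a)
  if (n < 2L) stop("need at least two raters for a paired comparison")
  dif <- errors_a - errors_b
  m <- mean(dif); s <- sd(dif)
  if (s == 0) {
    tstat <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = tstat, df = n - 1L, p = if (m == 0) 1 else 0,
                d = if (m == 0) 0 else sign(m) * Inf,
                mean_diff = m, degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, df = n - 1L,
       p = 2 * pt(-abs(tstat), df = n - 1L),
       d = m / s, mean_diff = m, degenerate = FALSE)
}

#' Chance-level mean zero-one error of a uniform random predictor
#'
#' A predictor drawing uniformly among R categories is wrong with
#' probability `(R-1)/R` regardless of the truth: 0.8 on a 5-point scale.
#'
#' @param R number of categories.
#' @return `(R - 1) / R`.
#' @export
chance_mze <- function(R = 5L) (R - 1) / R
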