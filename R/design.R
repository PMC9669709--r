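## Sequential experimental design: a random exploration phase followed by an
## adaptive phase that presents the stimulus maximizing the upper confidence
## bound of the current GPOR fit over a fixed candidate grid.

#' Session configuration for a rating experiment
#'
#' Defaults mirror a 5-point Likert session in a 3-PC face space: 20
#' discarded practice trials, 45 uniform random test trials on the +/-2 SD
#' box, then 15 adaptive trials selected by UCB over the 0.4-step grid.
#'
#' @param n_random number of random-phase test trials.
#' @param n_adaptive number of adaptive-phase test trials.
#' @param n_practice practice trials drawn from the random stream and
#'   discarded before analysis.
#' @param bounds symmetric half-width of the stimulus box in SD units.
#' @param grid_step candidate-grid step in SD units; must divide `2*bounds`.
#' @param D stimulus dimensionality (number of PCs).
#' @param R number of ordinal response categories.
#' @param ucb_beta `"log_over_n"` for `beta(N) = log(N)/N` (default) or
#'   `"sqrt_log_over_n"` for the conventional GP-UCB `sqrt(log(N)/N)`.
#' @param refit_every refit hyperparameters every this many adaptive trials
#'   (the latent vector is refit before every selection); 1 = full refit
#'   each trial.
#' @param n_restarts,maxit hyperparameter-fitting effort, see
#'   [fit_hyperparams()].
#' @param seed integer seed driving the whole session stream.
#' @return an object of class `session_config`.
#' @export
session_config <- function(n_random = 45L, n_adaptive = 15L, n_practice = 20L,
                           bounds = 2, grid_step = 0.4, D = 3L, R = 5L,
                           ucb_beta = c("log_over_n", "sqrt_log_over_n"),
                           refit_every = 1L, n_restarts = 2L, maxit = 300L,
                           seed = 1L) {
  ucb_beta <- match.arg(ucb_beta)
  if (n_random < 0 || n_adaptive < 0 || n_practice < 0) {
    stop("trial counts must be nonnegative")
  }
  steps <- 2 * bounds / grid_step
  if (abs(steps - round(steps)) > 1e-9) {
    stop("grid_step must divide the bounds span")
  }
  structure(list(n_random = as.integer(n_random),
                 n_adaptive = as.integer(n_adaptive),
                 n_practice = as.integer(n_practice),
                 bounds = bounds, grid_step = grid_step,
                 D = as.integer(D), R = as.integer(R), ucb_beta = ucb_beta,
                 refit_every = as.integer(refit_every),
                 n_restarts = as.integer(n_restarts),
                 maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Candidate grid over the stimulus box
#'
#' All combinations of `seq(-bounds, bounds, by = step)` per dimension, in
#' lexicographic row order (first coordinate most significant).
#'
#' @param D dimensionality.
#' @param bounds symmetric half-width in SD units.
#' @param step grid step in SD units.
#' @return an `(2*bounds/step + 1)^D` x D matrix.
#' @export
sd_grid <- function(D = 3L, bounds = 2, step = 0.4) {
  steps <- 2 * bounds / step
  if (abs(steps - round(steps)) > 1e-9) stop("step must divide the span")
  ax <- seq(-bounds, bounds, length.out = round(steps) + 1L)
  g <- as.matrix(expand.grid(rev(replicate(D, ax, simplify = FALSE)),
                             KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_len(D)), drop = FALSE]
  dimnames(g) <- list(NULL, paste0("pc", seq_len(D)))
  g
}

#' Upper-confidence-bound acquisition values
#'
#' `UCB = mu + beta(N) * sigma` with `beta(N) = log(N)/N` by default, or
#' `sqrt(log(N)/N)` under `beta = "sqrt_log_over_n"`.
#'
#' @param mu predictive means on the candidate set.
#' @param sigma predictive standard deviations (>= 0), same length.
#' @param N number of trials observed so far (>= 1).
#' @param beta exploration-coefficient rule.
#' @return numeric vector of acquisition values.
#' @export
ucb_scores <- function(mu, sigma, N,
                       beta = c("log_over_n", "sqrt_log_over_n")) {
  beta <- match.arg(beta)
  if (length(mu) != length(sigma)) stop("mu and sigma must have equal length")
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  if (N < 1) stop("UCB coefficient undefined for N < 1")
  coef <- log(N) / N
  if (beta == "sqrt_log_over_n") coef <- sqrt(coef)
  mu + coef * sigma
}

#' Select the next adaptive stimulus by UCB maximization
#'
#' Evaluates the latent predictive on the candidate grid and returns the
#' grid point with the highest UCB; ties resolve to the lexicographically
#' smallest coordinate.
#'
#' @param model a fitted [fit_gpor()] model on the response history.
#' @param grid candidate coordinate matrix (rows = candidates).
#' @param N trial count entering the exploration coefficient.
#' @param beta see [ucb_scores()].
#' @return a length-D coordinate vector.
#' @export
select_next_stimulus <- function(model, grid, N,
                                 beta = c("log_over_n", "sqrt_log_over_n")) {
  beta <- match.arg(beta)
  if (!inherits(model, "gpor_model")) stop("`model` must be a fitted gpor_model")
  pl <- predict_latent(model, grid)
  u <- ucb_scores(pl$mu, sqrt(pl$var), N, beta)
  best <- which(u >= max(u) - 1e-12)
  as.numeric(grid[lex_min_index(grid, best), ])
}

#' Draw a uniform random stimulus from the session box
#'
#' @param D dimensionality.
#' @param bounds symmetric half-width in SD units.
#' @return a length-D coordinate drawn uniformly from `[-bounds, bounds]^D`
#'   using the current RNG stream.
#' @export
random_stimulus <- function(D, bounds = 2) {
  runif(D, -bounds, bounds)
}

#' Run one simulated rating session
#'
#' Generates and discards the practice trials, presents `n_random` uniform
#' random stimuli, then `n_adaptive` UCB-selected stimuli, querying
#' `responder(x)` for an ordinal label after each presentation.  Before each
#' adaptive selection the latent vector is refit on the accumulated history;
#' hyperparameters are refit every `refit_every` adaptive trials.
#'
#' @param responder a function mapping a length-D coordinate to a label in
#'   1..R.
#' @param config a [session_config()].
#' @param hyper optional fixed [gpor_hyper()]; when supplied,
#'   hyperparameters are never refit during the session.
#' @return an [ordinal_data()] with the `n_random + n_adaptive` test trials
#'   in presentation order; attribute `phase` marks each trial as
#'   `"random"` or `"adaptive"`.
#' @export
run_session <- function(responder, config, hyper = NULL) {
  stopifnot(inherits(config, "session_config"))
  D <- config$D; R <- config$R
  grid <- sd_grid(D, config$bounds, config$grid_step)
  with_seed(config$seed, {
    ask <- function(x) {
      y <- responder(x)
      if (!is.numeric(y) || length(y) != 1L || is.na(y) ||
          y != round(y) || y < 1 || y > R) {
        stop("responder returned an invalid label: ", paste(y, collapse = ","))
      }
      as.integer(y)
    }
    for (i in seq_len(config$n_practice)) {  # practice: drawn and discarded
      ask(random_stimulus(D, config$bounds))
    }
    X <- matrix(NA_real_, config$n_random + config$n_adaptive, D)
    y <- integer(0)
    for (i in seq_len(config$n_random)) {
      X[i, ] <- random_stimulus(D, config$bounds)
      y[i] <- ask(X[i, ])
    }
    cur_hyper <- hyper
    for (j in seq_len(config$n_adaptive)) {
      N <- config$n_random + j - 1L
      hist <- ordinal_data(X[seq_len(N), , drop = FALSE], y, R)
      if (is.null(hyper) &&
          (j == 1L || (j - 1L) %% config$refit_every == 0L)) {
        cur_hyper <- fit_hyperparams(hist, n_restarts = config$n_restarts,
                                     seed = config$seed + 7L * j,
                                     maxit = config$maxit)
      }
      model <- fit_gpor(hist, cur_hyper)
      X[N + 1L, ] <- select_next_stimulus(model, grid, N,
                                          beta = config$ucb_beta)
      y[N + 1L] <- ask(X[N + 1L, ])
    }
    out <- ordinal_data(X, y, R)
    attr(out, "phase") <- rep(c("random", "adaptive"),
                              c(config$n_random, config$n_adaptive))
    out
  })
}
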