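## Pooling utility surfaces across raters: evaluate each fitted model on the
## standard +/-2 SD grid, average the Gaussian predictives as an
## equal-weight mixture (pooled mean and mixture variance), locate the
## extrema of the averaged utility, and test the maximum against zero.

#' Evaluate a fitted model's latent utility on a grid
#'
#' @param model a fitted [fit_gpor()] model.
#' @param grid candidate coordinate matrix, or `NULL` to use the default
#'   [sd_grid()] at the model's dimensionality (+/-2 SD, step 0.4).
#' @param bounds,step grid geometry when `grid` is `NULL`.
#' @return an object of class `utility_grid`: `coords` (lexicographic row
#'   order), `mu`, `var`.
#' @export
evaluate_on_grid <- function(model, grid = NULL, bounds = 2, step = 0.4) {
  if (is.null(grid)) grid <- sd_grid(model$data$D, bounds, step)
  grid <- as.matrix(grid)
  pl <- predict_latent(model, grid)
  structure(list(coords = grid, mu = pl$mu, var = pl$var),
            class = "utility_grid")
}

#' Average utility grids across raters
#'
#' Equal-weight Gaussian-mixture moments at every grid point:
#' `mu_S = mean_s mu_s` and `var_S = mean_s (mu_s^2 + var_s) - mu_S^2`.
#' The mixture variance dominates the mean within-rater variance (law of
#' total variance), with equality iff all rater means agree.
#'
#' @param grids list of [evaluate_on_grid()] results on identical coords.
#' @return an object of class `averaged_utility` with `coords`, `mu_S`,
#'   `var_S`, `M` (rater count) and the extrema `x_star` / `x_minus` from
#'   [locate_extrema()].
#' @export
average_utilities <- function(grids) {
  if (length(grids) < 1L) stop("need at least one utility grid")
  coords <- grids[[1]]$coords
  for (g in grids) {
    if (!isTRUE(all.equal(g$coords, coords, tolerance = 1e-12))) {
      stop("utility grids evaluated on mismatched coordinates")
    }
  }
  MU <- vapply(grids, function(g) g$mu, numeric(nrow(coords)))
  V <- vapply(grids, function(g) g$var, numeric(nrow(coords)))
  MU <- matrix(MU, nrow = nrow(coords)); V <- matrix(V, nrow = nrow(coords))
  mu_S <- rowMeans(MU)
  var_S <- rowMeans(MU^2 + V) - mu_S^2
  var_S <- pmax(var_S, 0)
  out <- structure(list(coords = coords, mu_S = mu_S, var_S = var_S,
                        M = length(grids)),
                   class = "averaged_utility")
  ex <- locate_extrema(out)
  out$x_star <- ex$x_star
  out$x_minus <- ex$x_minus
  out
}

#' Locate the extrema of an averaged utility surface
#'
#' Argmax and argmin of the pooled mean over the grid; ties resolve to the
#' lexicographically smallest coordinate.
#'
#' @param avg an [average_utilities()] object (or any list with `coords`
#'   and `mu_S`).
#' @return a list with `x_star` (argmax), `x_minus` (argmin) and their row
#'   indices `i_star`, `i_minus`.
#' @export
locate_extrema <- function(avg) {
  mu <- avg$mu_S
  if (length(mu) == 0L) stop("empty grid")
  i_star <- lex_min_index(avg$coords, which(mu >= max(mu) - 0))
  i_minus <- lex_min_index(avg$coords, which(mu <= min(mu) + 0))
  list(x_star = as.numeric(avg$coords[i_star, ]),
       x_minus = as.numeric(avg$coords[i_minus, ]),
       i_star = i_star, i_minus = i_minus)
}

#' Probability that the latent utility is at most zero
#'
#' Under a Gaussian predictive `N(mu, var)` the exceedance probability
#' `P(f <= 0) = Phi(-mu / sqrt(var))`; a small value certifies the utility
#' at that point is significantly greater than zero.
#'
#' @param mu predictive mean.
#' @param var predictive variance (>= 0).
#' @return a probability; with `var = 0` returns 0 or 1 by the sign of
#'   `mu` (attribute `degenerate = TRUE`).
#' @export
exceedance_probability <- function(mu, var) {
  if (any(var < 0)) stop("variance must be nonnegative")
  if (any(var == 0)) {
    p <- ifelse(var == 0, as.numeric(mu <= 0), pnorm(-mu / sqrt(var)))
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  pnorm(-mu / sqrt(var))
}
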