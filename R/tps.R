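## Thin-plate spline warps between landmark configurations.
##
## The 2-D TPS minimizes bending energy among interpolants; with the radial
## basis U(r) = r^2 log r^2 (U(0) = 0) the warp is the solution of the dense
## linear system  [K + lambda I, P; P', 0] [w; a] = [v; 0]  solved per target
## coordinate, where P = [1, x, y] carries the affine part.

tps_U <- function(r2) {
  # U(r) = r^2 log(r^2), continuously extended by 0 at r = 0
  out <- numeric(length(r2))
  pos <- r2 > 0
  out[pos] <- r2[pos] * log(r2[pos])
  out
}

tps_kernel_matrix <- function(A, B) {
  # pairwise U between rows of A (n x 2) and rows of B (m x 2)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  matrix(tps_U(d2), nrow(A), nrow(B))
}

#' Fit a thin-plate spline warp between two landmark configurations
#'
#' @param source K x 2 matrix of source landmarks (K >= 3, not collinear).
#' @param target K x 2 matrix of corresponding target landmarks.
#' @param lambda_reg nonnegative smoothing parameter; 0 (default) gives exact
#'   interpolation.
#' @return an object of class `tps_warp` with the affine coefficients
#'   (3 x 2), non-affine weights (K x 2), the source/target landmarks and
#'   the bending energy (summed over the two target coordinates).
#' @export
tps_fit <- function(source, target, lambda_reg = 0) {
  src <- as_landmarks(source)
  tgt <- as_landmarks(target)
  if (nrow(src) != nrow(tgt)) stop("source and target must have equal K")
  if (lambda_reg < 0) stop("lambda_reg must be nonnegative")
  K <- nrow(src)
  Kmat <- tps_kernel_matrix(src, src) + diag(lambda_reg, K)
  P <- cbind(1, src)
  L <- rbind(cbind(Kmat, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(tgt, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular TPS system (collinear source landmarks?): ",
         conditionMessage(e))
  })
  w <- sol[seq_len(K), , drop = FALSE]
  a <- sol[K + 1:3, , drop = FALSE]
  be <- sum(diag(crossprod(w, tps_kernel_matrix(src, src) %*% w)))
  structure(list(source = src, target = tgt, affine = a, weights = w,
                 bending_energy = max(be, 0), lambda = lambda_reg),
            class = "tps_warp")
}

#' Apply a fitted thin-plate spline warp to points
#'
#' Evaluates the affine part plus the radial-basis expansion at each point.
#' With `lambda_reg = 0` the warp maps the source landmarks exactly onto the
#' target landmarks.
#'
#' @param warp a [tps_fit()] object.
#' @param points an m x 2 matrix of coordinates to warp.
#' @return an m x 2 matrix of warped coordinates.
#' @export
tps_apply <- function(warp, points) {
  if (!inherits(warp, "tps_warp")) stop("`warp` must be a tps_warp")
  pts <- matrix(as.numeric(as.matrix(points)), ncol = 2)
  U <- tps_kernel_matrix(pts, warp$source)
  cbind(1, pts) %*% warp$affine + U %*% warp$weights
}

#' Warp a rectangular grayscale grid through a TPS
#'
#' Convenience wrapper for synthetic texture experiments: warps the pixel
#' center coordinates of a grayscale grid through the *inverse* use of the
#' warp (target-to-source fitted separately by the caller) and bilinearly
#' resamples the image.  Real photograph handling is out of scope; this
#' operates on plain numeric matrices only.
#'
#' @param warp a [tps_fit()] object mapping output coordinates to input
#'   coordinates (i.e., fit with `source` = output landmarks).
#' @param image numeric matrix, rows = y (top to bottom), columns = x.
#' @param xlim,ylim coordinate ranges spanned by the image columns and rows.
#' @return a numeric matrix of the warped image, same size as `image`.
#' @export
tps_warp_image <- function(warp, image, xlim = c(0, 1), ylim = c(0, 1)) {
  nr <- nrow(image); nc <- ncol(image)
  xs <- seq(xlim[1], xlim[2], length.out = nc)
  ys <- seq(ylim[1], ylim[2], length.out = nr)
  grid <- cbind(rep(xs, each = nr), rep(ys, times = nc))
  mapped <- tps_apply(warp, grid)
  # bilinear sample of `image` at mapped coordinates
  gx <- (mapped[, 1] - xlim[1]) / diff(xlim) * (nc - 1) + 1
  gy <- (mapped[, 2] - ylim[1]) / diff(ylim) * (nr - 1) + 1
  gx <- pmin(pmax(gx, 1), nc); gy <- pmin(pmax(gy, 1), nr)
  x0 <- pmin(floor(gx), nc - 1); y0 <- pmin(floor(gy), nr - 1)
  fx <- gx - x0; fy <- gy - y0
  v <- image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    image[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    image[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    image[cbind(y0 + 1, x0 + 1)] * fx * fy
  matrix(v, nr, nc)
}
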