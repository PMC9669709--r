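#' Centroid size of a landmark configuration
#'
#' The standardization scale used throughout geometric morphometrics: by
#' default the square root of the summed squared distances from each landmark
#' to the configuration centroid (Bookstein convention).  `type = "raw"`
#' returns the un-rooted sum of squares, kept as a sensitivity option.
#'
#' @param config a K x 2 numeric matrix of landmark coordinates.
#' @param type `"root"` (default) or `"raw"`.
#' @return a positive scalar.
#' @export
centroid_size <- function(config, type = c("root", "raw")) {
  type <- match.arg(type)
  m <- as_landmarks(config)
  c0 <- colMeans(m)
  ss <- sum(sweep(m, 2, c0)^2)
  if (type == "root") sqrt(ss) else ss
}

#' Translate a configuration to the origin and scale it to unit centroid size
#'
#' @inheritParams centroid_size
#' @return a K x 2 matrix with centroid exactly at the origin and centroid
#'   size 1.
#' @export
center_and_scale <- function(config, type = c("root", "raw")) {
  type <- match.arg(type)
  m <- as_landmarks(config)
  m <- sweep(m, 2, colMeans(m))
  cs <- if (type == "root") sqrt(sum(m^2)) else sum(m^2)
  if (cs < 1e-12) stop("degenerate configuration: all landmarks coincide")
  m / cs
}

# Optimal rotation (no reflection) aligning `m` onto `target`, both assumed
# centered.  2-D orthogonal Procrustes via SVD with determinant forced +1.
procrustes_rotation <- function(m, target) {
  s <- svd(crossprod(target, m))  # t(target) %*% m, 2 x 2
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  R
}

#' Generalized Procrustes alignment of a set of landmark configurations
#'
#' Iteratively removes translation, scale and rotation: every configuration
#' is centered and scaled to unit centroid size, rotated onto the current
#' mean shape by 2-D orthogonal Procrustes (reflections excluded), and the
#' mean is recomputed and re-standardized, until the mean shape moves by less
#' than `tol` between iterations.
#'
#' @param configs a list of K x 2 matrices (or a K x 2 x n array) with a
#'   common landmark ordering.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   mean shape.
#' @param max_iter maximum number of alignment sweeps.
#' @param centroid_size_type `"root"` or `"raw"`, see [centroid_size()].
#' @return an object of class `procrustes_fit` with elements `aligned`
#'   (K x 2 x n array), `mean_shape` (K x 2 matrix, unit centroid size),
#'   `iterations` and `converged`.
#' @export
gpa_align <- function(configs, tol = 1e-8, max_iter = 200,
                      centroid_size_type = c("root", "raw")) {
  centroid_size_type <- match.arg(centroid_size_type)
  arr <- as_landmark_array(configs)
  n <- dim(arr)[3]
  if (n < 2L) stop("GPA needs at least two configurations")
  for (i in seq_len(n)) arr[, , i] <- center_and_scale(arr[, , i], centroid_size_type)

  mean_shape <- center_and_scale(apply(arr, c(1, 2), mean), centroid_size_type)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      arr[, , i] <- arr[, , i] %*% procrustes_rotation(arr[, , i], mean_shape)
    }
    new_mean <- center_and_scale(apply(arr, c(1, 2), mean), centroid_size_type)
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(aligned = arr, mean_shape = mean_shape,
                 iterations = iter, converged = converged),
            class = "procrustes_fit")
}

#' Bilateral symmetry map
#'
#' Pairs left/right landmark indices and lists unpaired midline landmarks.
#' Every landmark index must appear exactly once across `pairs` and
#' `midline`.
#'
#' @param pairs a two-column matrix (left index, right index).
#' @param midline integer vector of midline landmark indices.
#' @param n_landmarks total landmark count K.
#' @return an object of class `symmetry_map`.
#' @export
symmetry_map <- function(pairs, midline = integer(), n_landmarks) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  all_idx <- c(as.vector(pairs), midline)
  if (anyDuplicated(all_idx)) stop("symmetry map: duplicated landmark index")
  if (!setequal(all_idx, seq_len(n_landmarks)) ||
      length(all_idx) != n_landmarks) {
    stop("symmetry map must cover each of the ", n_landmarks,
         " landmark indices exactly once")
  }
  structure(list(pairs = pairs, midline = midline, n_landmarks = n_landmarks),
            class = "symmetry_map")
}

# Permutation sending each landmark to its mirror partner (midline fixed).
symmetry_permutation <- function(map) {
  perm <- seq_len(map$n_landmarks)
  perm[map$pairs[, 1]] <- map$pairs[, 2]
  perm[map$pairs[, 2]] <- map$pairs[, 1]
  perm
}

# Mirror a centered configuration: negate x and swap paired landmark labels.
reflect_relabel <- function(m, map) {
  refl <- m
  refl[, 1] <- -refl[, 1]
  refl[symmetry_permutation(map), , drop = FALSE]
}

#' Symmetrize a configuration under a bilateral symmetry map
#'
#' A mirror-reversed, relabeled copy of the configuration is Procrustes
#' aligned to the original and the two are averaged.  The rotation bringing
#' the reflection onto the original is split evenly between the two copies,
#' so the returned shape is exactly bilaterally symmetric (up to floating
#' point) about the vertical axis through its centroid.  The input's
#' centroid and centroid size are preserved.
#'
#' @param config a K x 2 landmark matrix.
#' @param map a [symmetry_map()] covering all K landmarks.
#' @return a K x 2 matrix, bilaterally symmetric under `map`.
#' @export
symmetrize <- function(config, map) {
  m <- as_landmarks(config)
  if (!inherits(map, "symmetry_map")) stop("`map` must be a symmetry_map")
  if (map$n_landmarks != nrow(m)) stop("symmetry map does not match K")
  cen <- colMeans(m)
  mc <- sweep(m, 2, cen)
  size <- sqrt(sum(mc^2))
  if (size < 1e-12) stop("degenerate configuration: all landmarks coincide")
  u <- mc / size
  refl <- reflect_relabel(u, map)
  # Optimal rotation of the reflection onto the original, then split it:
  # rotate the original by -theta/2 and the reflection by +theta/2 before
  # averaging, which makes the average an exact fixed point of the mirror
  # operation (mirroring conjugates a rotation into its inverse).
  R <- procrustes_rotation(refl, u)
  theta <- atan2(R[2, 1], R[1, 1])
  half <- function(a) matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  sym <- (u %*% half(-theta / 2) + refl %*% half(theta / 2)) / 2
  sweep(sym * size, 2, -cen)
}

#' Asymmetry of a configuration under a symmetry map
#'
#' Root-mean-square distance between a centered configuration and its
#' mirror-relabeled copy; zero iff the shape is bilaterally symmetric about
#' the vertical axis through its centroid.
#'
#' @inheritParams symmetrize
#' @return a nonnegative scalar.
#' @export
asymmetry_score <- function(config, map) {
  m <- as_landmarks(config)
  mc <- sweep(m, 2, colMeans(m))
  sqrt(mean((mc - reflect_relabel(mc, map))^2))
}

#' Build a face space from aligned landmark configurations
#'
#' Principal component analysis of the covariance matrix of the flattened
#' coordinate vectors (x1, y1, ..., xK, yK).  Scores along each retained
#' component are stored as per-component standard deviations so that
#' downstream coordinates can be expressed in SD units.
#'
#' @param aligned list of K x 2 matrices or a K x 2 x n array of aligned
#'   (and typically symmetrized) configurations.
#' @param n_pcs number of principal components to retain.
#' @return an object of class `face_space` with elements `mean_shape`
#'   (K x 2), `loadings` (2K x n_pcs, orthonormal columns), `pc_sd`
#'   (score SD per component), `explained_ratio` (fraction of total variance
#'   per retained component) and `n_landmarks`.
#' @export
fit_face_space <- function(aligned, n_pcs = 3L) {
  arr <- as_landmark_array(aligned)
  K <- dim(arr)[1]
  n <- dim(arr)[3]
  if (n < 2L) stop("need at least two configurations")
  # flatten: row i = (x1, y1, ..., xK, yK) of configuration i
  X <- t(apply(arr, 3, function(m) as.vector(t(m))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc / sqrt(n - 1))
  eig <- sv$d^2
  rank <- sum(eig > max(eig) * 1e-12)
  if (n_pcs > rank) {
    stop("n_pcs = ", n_pcs, " exceeds the achievable rank ", rank)
  }
  total <- sum(eig)
  structure(list(
    mean_shape = matrix(mu, ncol = 2, byrow = TRUE),
    loadings = sv$v[, seq_len(n_pcs), drop = FALSE],
    pc_sd = sv$d[seq_len(n_pcs)],
    explained_ratio = eig[seq_len(n_pcs)] / total,
    n_landmarks = K
  ), class = "face_space")
}

#' @export
print.face_space <- function(x, ...) {
  cat("Face space:", x$n_landmarks, "landmarks,",
      ncol(x$loadings), "principal components\n")
  cat("  score SD:", format(x$pc_sd, digits = 4), "\n")
  cat("  explained variance ratio:",
      format(x$explained_ratio, digits = 4), "\n")
  invisible(x)
}

#' Render a landmark shape at face-space coordinates
#'
#' Maps a coordinate vector in per-component SD units back to a landmark
#' configuration: `mean_shape + sum_d scores_sd[d] * pc_sd[d] * loading_d`.
#'
#' @param space a [fit_face_space()] object.
#' @param scores_sd numeric vector of PC coordinates in SD units (length at
#'   most the number of retained components; missing trailing entries are 0).
#' @return a K x 2 landmark matrix.
#' @export
scores_to_landmarks <- function(space, scores_sd) {
  D <- ncol(space$loadings)
  scores_sd <- as.numeric(scores_sd)
  if (length(scores_sd) > D) stop("more scores than retained components")
  s <- c(scores_sd, rep(0, D - length(scores_sd)))
  flat <- as.vector(t(space$mean_shape)) +
    as.vector(space$loadings %*% (s * space$pc_sd))
  matrix(flat, ncol = 2, byrow = TRUE)
}

#' Project a landmark shape onto face-space coordinates
#'
#' Inverse of [scores_to_landmarks()] for shapes in the span of the retained
#' components: projects the flattened deviation from the mean shape onto the
#' loadings and rescales to SD units.
#'
#' @param space a [fit_face_space()] object.
#' @param config a K x 2 landmark matrix.
#' @return numeric vector of PC coordinates in SD units.
#' @export
landmarks_to_scores <- function(space, config) {
  m <- as_landmarks(config)
  dev <- as.vector(t(m)) - as.vector(t(space$mean_shape))
  as.vector(crossprod(space$loadings, dev)) / space$pc_sd
}
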