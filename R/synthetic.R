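## Synthetic data: landmark populations with planted principal-component
## structure, and simulated raters that respond through the same generative
## model the GPOR likelihood assumes (latent utility + Gaussian noise +
## ordered thresholds).  Stands in for unavailable photographs and human
## raters in end-to-end recovery tests.

#' Symmetric face-like landmark template
#'
#' Arranges `n_landmarks` points into a stylized frontal face: an elliptical
#' outline plus mirrored feature clusters (eyes, brows, nose, mouth) and a
#' few midline points, bilaterally symmetric about x = 0.  Returns both the
#' template and its [symmetry_map()].
#'
#' @param n_landmarks total landmark count (>= 10).
#' @return a list with `points` (K x 2) and `map`.
#' @export
face_template <- function(n_landmarks = 80L) {
  K <- as.integer(n_landmarks)
  if (K < 10L) stop("need at least 10 landmarks for a face template")
  n_mid <- if (K %% 2L == 0L) 4L else 5L
  n_pairs <- (K - n_mid) %/% 2L
  # midline: forehead, nose bridge, nose tip, chin (+ lip center if odd)
  mid_y <- seq(0.95, -0.95, length.out = n_mid)
  midline_pts <- cbind(0, mid_y)
  # right-side cluster centers (x > 0) and relative sizes
  clusters <- list(
    outline = list(c(0.75, 0.0), 0.45),
    eye     = list(c(0.35, 0.30), 0.12),
    brow    = list(c(0.35, 0.55), 0.10),
    nose    = list(c(0.12, -0.05), 0.08),
    mouth   = list(c(0.25, -0.45), 0.12)
  )
  share <- c(outline = 0.4, eye = 0.2, brow = 0.1, nose = 0.1, mouth = 0.2)
  counts <- floor(share * n_pairs)
  rem <- n_pairs - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  right <- do.call(rbind, lapply(names(clusters), function(nm) {
    k <- counts[[nm]]
    if (k == 0L) return(NULL)
    cen <- clusters[[nm]][[1]]; rad <- clusters[[nm]][[2]]
    ang <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
    if (nm == "outline") {  # half ellipse on the right side
      ang <- seq(-pi / 2, pi / 2, length.out = k)
      cbind(0.75 * cos(ang * 0.9), 1.0 * sin(ang))
    } else {
      cbind(cen[1] + rad * cos(ang), cen[2] + rad * sin(ang))
    }
  }))
  right[, 1] <- pmax(right[, 1], 0.02)  # keep strictly on the right
  left <- cbind(-right[, 1], right[, 2])
  pts <- unname(rbind(right, left, midline_pts))
  dimnames(pts) <- NULL
  pairs <- cbind(n_pairs + seq_len(n_pairs), seq_len(n_pairs))  # (left, right)
  map <- symmetry_map(pairs, midline = 2L * n_pairs + seq_len(n_mid),
                      n_landmarks = K)
  list(points = pts, map = map)
}

# Reflect-relabel operator on flattened (x1,y1,...,xK,yK) vectors.
flat_reflect <- function(v, map) {
  m <- matrix(v, ncol = 2, byrow = TRUE)
  as.vector(t(reflect_relabel(m, map)))
}

#' Generate a landmark population with planted principal components
#'
#' Each face is the template plus a low-rank symmetric deformation:
#' `template + sum_k score_k * factor_sds[k] * loading_k + noise`, with
#' standard-normal scores, mutually orthonormal loadings that are exactly
#' bilaterally symmetric under the map (so symmetrization is near-lossless)
#' and isotropic coordinate noise.  Optionally each face is additionally
#' rotated, scaled and translated at random so the population exercises the
#' full Procrustes pipeline.
#'
#' @param n_faces number of faces.
#' @param n_landmarks landmarks per face.
#' @param factor_sds decreasing vector of planted score standard deviations.
#' @param noise_sd isotropic landmark noise SD.
#' @param map optional [symmetry_map()]; defaults to the template's.
#' @param transform_jitter apply a random similarity transform per face.
#' @param seed RNG seed.
#' @return a list of K x 2 matrices with attributes `map`, `template`,
#'   `loadings` (2K x n_factors) and `scores`.
#' @export
generate_shape_population <- function(n_faces = 500L, n_landmarks = 80L,
                                      factor_sds = c(0.04, 0.028, 0.02),
                                      noise_sd = 0.002, map = NULL,
                                      transform_jitter = TRUE, seed = 1L) {
  if (is.unsorted(rev(factor_sds))) stop("factor_sds must be decreasing")
  if (n_faces <= length(factor_sds) + 1L) {
    stop("n_faces must exceed the number of planted factors")
  }
  tmpl <- face_template(n_landmarks)
  if (is.null(map)) map <- tmpl$map
  if (map$n_landmarks != n_landmarks) stop("symmetry map does not match K")
  base <- center_and_scale(tmpl$points)
  flat0 <- as.vector(t(base))
  P <- 2L * n_landmarks
  with_seed(seed, {
    nf <- length(factor_sds)
    # symmetric orthonormal loadings
    L <- matrix(0, P, nf)
    for (k in seq_len(nf)) {
      v <- rnorm(P)
      v <- (v + flat_reflect(v, map)) / 2
      if (k > 1L) v <- v - L[, 1:(k - 1), drop = FALSE] %*%
          crossprod(L[, 1:(k - 1), drop = FALSE], v)
      L[, k] <- v / sqrt(sum(v^2))
    }
    scores <- matrix(rnorm(n_faces * nf), n_faces, nf)
    out <- vector("list", n_faces)
    for (i in seq_len(n_faces)) {
      flat <- flat0 + as.vector(L %*% (scores[i, ] * factor_sds)) +
        rnorm(P, sd = noise_sd)
      m <- matrix(flat, ncol = 2, byrow = TRUE)
      if (transform_jitter) {
        th <- runif(1, -pi / 6, pi / 6)
        Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
        m <- m %*% Rm * exp(runif(1, -0.3, 0.3))
        m <- sweep(m, 2, runif(2, -0.5, 0.5), "+")
      }
      out[[i]] <- m
    }
    attr(out, "map") <- map
    attr(out, "template") <- base
    attr(out, "loadings") <- L
    attr(out, "scores") <- scores
    out
  })
}

#' Ground-truth utility function for simulations
#'
#' Three families over the +/-2 SD box:
#' * `quadratic_peak`: `amplitude - curvature * ||x - peak||^2`;
#' * `bimodal`: pointwise maximum of two Gaussian bumps with stated peak
#'   locations and heights;
#' * `gp_sample`: a seeded draw from a GP with an ARD kernel on a fixed
#'   0.4-step lattice, extended by multilinear interpolation.
#'
#' @param kind one of `"quadratic_peak"`, `"bimodal"`, `"gp_sample"`.
#' @param D dimensionality.
#' @param peak,curvature,amplitude quadratic-peak parameters.
#' @param peaks,heights,widths bimodal parameters: 2 x D matrix of peak
#'   locations, their heights, bump widths (SD units).
#' @param eta,gp_scale,seed gp-sample parameters.
#' @return an object of class `true_utility`.
#' @export
true_utility <- function(kind = c("quadratic_peak", "bimodal", "gp_sample"),
                         D = 3L, peak = rep(0, D), curvature = 0.25,
                         amplitude = 2, peaks = NULL, heights = c(2, 1),
                         widths = c(0.8, 0.8), eta = rep(1, D), gp_scale = 1.5,
                         seed = 1L) {
  kind <- match.arg(kind)
  u <- list(kind = kind, D = as.integer(D), amplitude = amplitude)
  if (kind == "quadratic_peak") {
    stopifnot(length(peak) == D)
    u$peak <- as.numeric(peak); u$curvature <- curvature
  } else if (kind == "bimodal") {
    if (is.null(peaks)) peaks <- rbind(rep(-1, D), rep(1, D))
    u$peaks <- matrix(peaks, ncol = D); u$heights <- heights; u$widths <- widths
  } else {
    ax <- seq(-2, 2, by = 0.4)
    lat <- sd_grid(D, 2, 0.4)
    Kmat <- ard_kernel(lat, lat, eta) * gp_scale^2
    vals <- with_seed(seed, {
      U <- chol(Kmat + diag(1e-8, nrow(lat)))
      as.vector(crossprod(U, rnorm(nrow(lat))))
    })
    u$lattice_axis <- ax; u$lattice_values <- vals; u$eta <- eta
  }
  structure(u, class = "true_utility")
}

# Multilinear interpolation on the lexicographic lattice of true_utility.
interp_lattice <- function(u, X) {
  ax <- u$lattice_axis
  n <- length(ax); D <- u$D
  step <- ax[2] - ax[1]
  vapply(seq_len(nrow(X)), function(i) {
    x <- pmin(pmax(X[i, ], ax[1]), ax[n])
    i0 <- pmin(floor((x - ax[1]) / step) + 1, n - 1)
    fr <- (x - ax[i0]) / step
    corners <- expand.grid(rep(list(0:1), D))
    val <- 0
    for (r in seq_len(nrow(corners))) {
      cc <- as.numeric(corners[r, ])
      idx <- i0 + cc
      # lexicographic flat index: first dimension most significant
      flat <- 1 + sum((idx - 1) * n^((D - 1):0))
      w <- prod(ifelse(cc == 1, fr, 1 - fr))
      val <- val + w * u$lattice_values[flat]
    }
    val
  }, numeric(1))
}

#' Evaluate a ground-truth utility
#'
#' @param u a [true_utility()] object.
#' @param x a coordinate vector or matrix of row coordinates.
#' @return numeric vector of utility values.
#' @export
evaluate_true_utility <- function(u, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != u$D) stop("coordinate dimension mismatch")
  switch(u$kind,
    quadratic_peak = u$amplitude -
      u$curvature * rowSums(sweep(X, 2, u$peak)^2),
    bimodal = {
      vals <- vapply(seq_len(nrow(u$peaks)), function(k) {
        u$heights[k] *
          exp(-rowSums(sweep(X, 2, u$peaks[k, ])^2) / (2 * u$widths[k]^2))
      }, numeric(nrow(X)))
      apply(matrix(vals, nrow = nrow(X)), 1, max)
    },
    gp_sample = interp_lattice(u, X)
  )
}

#' Simulated ordinal rater
#'
#' Responds according to the thresholded-noisy-utility model: the label is
#' `s` iff `b_{s-1} < u(x) + delta <= b_s` with `delta ~ N(0, noise_sd^2)`
#' drawn from the rater's own reproducible RNG stream.
#'
#' @param utility a [true_utility()] object.
#' @param b strictly increasing thresholds (length R-1).
#' @param noise_sd response noise SD.
#' @param seed seed of the rater's private stream.
#' @return an object of class `sim_participant`.
#' @export
sim_participant <- function(utility, b = c(-1.5, -0.5, 0.5, 1.5),
                            noise_sd = 1, seed = 1L) {
  if (any(diff(b) <= 0)) stop("thresholds must be strictly increasing")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  state <- new.env(parent = emptyenv())
  state$rng <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  structure(list(utility = utility, b = as.numeric(b), noise_sd = noise_sd,
                 R = length(b) + 1L, seed = as.integer(seed), state = state),
            class = "sim_participant")
}

#' Draw an ordinal response from a simulated rater
#'
#' Advances the rater's private RNG stream; the global RNG is untouched.
#'
#' @param p a [sim_participant()].
#' @param x stimulus coordinate (length-D vector or m x D matrix).
#' @return integer label(s) in 1..R.
#' @export
simulate_response <- function(p, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  f <- evaluate_true_utility(p$utility, X)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", p$state$rng, envir = globalenv())
  delta <- rnorm(nrow(X), sd = p$noise_sd)
  p$state$rng <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  as.integer(findInterval(f + delta, p$b) + 1L)
}

#' Responder closure for [run_session()]
#'
#' @param p a [sim_participant()].
#' @return a function mapping a coordinate to a label.
#' @export
participant_responder <- function(p) {
  function(x) simulate_response(p, x)
}

#' Simulate a complete multi-rater study
#'
#' Creates `M` simulated raters whose quadratic-peak utilities share a peak
#' location plus per-rater Gaussian jitter, runs each through the
#' random-then-adaptive rating session, and returns their datasets along
#' with the ground truth.  Rater `i` uses seeds derived from `seed + i`, so
#' enlarging a study leaves existing raters' data unchanged.
#'
#' @param M number of raters.
#' @param config a [session_config()] (its `seed` is overridden per rater).
#' @param shared_peak length-D true peak shared across raters.
#' @param peak_jitter_sd SD of the per-rater peak jitter (per PC).
#' @param amplitude,curvature quadratic-peak parameters.
#' @param b,noise_sd response-model parameters.
#' @param seed study master seed.
#' @return a list of class `sim_study`: `datasets` (list of
#'   [ordinal_data()]), `participants`, `peaks` (M x D true peaks) and
#'   `shared_peak`.
#' @export
simulate_study <- function(M = 40L, config = session_config(),
                           shared_peak = c(-0.8, -0.4, 0.8),
                           peak_jitter_sd = 0.3, amplitude = 2,
                           curvature = 0.25, b = c(-1.5, -0.5, 0.5, 1.5),
                           noise_sd = 1, seed = 1L) {
  if (M < 1L) stop("M must be at least 1")
  D <- config$D
  stopifnot(length(shared_peak) == D)
  datasets <- vector("list", M)
  participants <- vector("list", M)
  peaks <- matrix(0, M, D)
  for (i in seq_len(M)) {
    peaks[i, ] <- with_seed(seed + i, {
      pmin(pmax(shared_peak + rnorm(D, sd = peak_jitter_sd),
                -config$bounds), config$bounds)
    })
    u <- true_utility("quadratic_peak", D = D, peak = peaks[i, ],
                      curvature = curvature, amplitude = amplitude)
    p <- sim_participant(u, b = b, noise_sd = noise_sd, seed = seed + i)
    cfg_i <- config
    cfg_i$seed <- as.integer(seed + i + 1000000L)
    datasets[[i]] <- run_session(participant_responder(p), cfg_i)
    participants[[i]] <- p
  }
  structure(list(datasets = datasets, participants = participants,
                 peaks = peaks, shared_peak = shared_peak, seed = seed),
            class = "sim_study")
}
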