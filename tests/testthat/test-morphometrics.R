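test_that("center_and_scale standardizes location and scale", {
  tri <- toy_triangle()
  out <- center_and_scale(tri)
  # direct arithmetic: centroid (1/3, 1/3), centroid size of centered shape
  cen <- sweep(tri, 2, c(1 / 3, 1 / 3))
  expect_equal(out, cen / sqrt(sum(cen^2)), tolerance = 1e-12)
  expect_equal(colMeans(out), c(0, 0), tolerance = 1e-15)
  expect_equal(centroid_size(out), 1, tolerance = 1e-12)

  # translation invariance
  expect_equal(center_and_scale(sweep(tri, 2, c(-5, 3))), out,
               tolerance = 1e-12)
  # raw convention squares the root size
  expect_equal(centroid_size(tri, "raw"), centroid_size(tri)^2)
  expect_error(center_and_scale(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA aligns similarity-transformed copies of one shape", {
  set.seed(11)
  base <- matrix(rnorm(20), ncol = 2)
  configs <- lapply(1:6, function(i) {
    s <- exp(runif(1, -1, 1))
    sweep(s * base %*% rot2(runif(1, -pi, pi)), 2, rnorm(2, sd = 3), "+")
  })
  g <- gpa_align(configs)
  expect_true(g$converged)
  for (i in 1:6) {
    expect_lt(max(abs(g$aligned[, , i] - g$aligned[, , 1])), 1e-6)
  }
  expect_equal(centroid_size(g$mean_shape), 1, tolerance = 1e-9)
  # duplicated single config: mean equals the standardized config up to
  # a common rotation
  g2 <- gpa_align(list(base, base))
  expect_equal(g2$mean_shape, g2$aligned[, , 1], tolerance = 1e-9)
})

test_that("pairwise Procrustes rotation matches a brute-force angle search", {
  set.seed(21)
  for (rep in 1:3) {
    a <- center_and_scale(matrix(rnorm(6), ncol = 2))
    b <- center_and_scale(matrix(rnorm(6), ncol = 2))
    R <- faceutility:::procrustes_rotation(b, a)
    thetas <- seq(-pi, pi, by = 1e-4)
    loss <- vapply(thetas, function(t) sum((b %*% rot2(t) - a)^2), 1)
    t_best <- thetas[which.min(loss)]
    expect_lt(sum((b %*% R - a)^2), min(loss) + 1e-9)
    expect_equal(sum((b %*% R - a)^2), sum((b %*% rot2(t_best) - a)^2),
                 tolerance = 1e-4)
    expect_equal(det(R), 1, tolerance = 1e-12)  # no reflection
  }
})

test_that("GPA result is invariant to input order", {
  set.seed(31)
  pop <- generate_shape_population(n_faces = 12, n_landmarks = 14, seed = 5)
  g1 <- gpa_align(pop)
  g2 <- gpa_align(pop[c(5:12, 1:4)])
  # align both means to a common reference before comparing
  R <- faceutility:::procrustes_rotation(g2$mean_shape, g1$mean_shape)
  expect_lt(max(abs(g2$mean_shape %*% R - g1$mean_shape)), 1e-6)
})

test_that("symmetrize produces exactly symmetric shapes and is idempotent", {
  tmpl <- face_template(20)
  map <- tmpl$map

  # fixed point: already-symmetric config returned unchanged
  sym_in <- tmpl$points
  expect_equal(symmetrize(sym_in, map), sym_in, tolerance = 1e-9)

  set.seed(41)
  noisy <- sym_in + matrix(rnorm(length(sym_in), sd = 0.05), ncol = 2)
  s1 <- symmetrize(noisy, map)
  expect_lt(asymmetry_score(s1, map), 1e-9)
  expect_equal(symmetrize(s1, map), s1, tolerance = 1e-9)
  # centroid and centroid size preserved
  expect_equal(colMeans(s1), colMeans(noisy), tolerance = 1e-9)

  bad_pairs <- matrix(c(1L, 1L), ncol = 2)
  expect_error(symmetry_map(bad_pairs, integer(), 2), "duplicated")
})

test_that("symmetrize matches the brute-force optimal symmetric shape", {
  tmpl <- face_template(10)
  map <- tmpl$map
  set.seed(43)
  cfg <- tmpl$points + matrix(rnorm(20, sd = 0.08), ncol = 2)
  u <- center_and_scale(cfg)
  refl <- faceutility:::reflect_relabel(u, map)
  # oracle: over a fine rotation grid, the best symmetric approximation of
  # u R(-t/2) is its symmetric part; pick the angle minimizing the
  # asymmetric residual
  obj <- vapply(seq(-pi / 2, pi / 2, by = 1e-4), function(t) {
    v <- (u %*% rot2(-t / 2) + refl %*% rot2(t / 2)) / 2
    sum((u %*% rot2(-t / 2) - v)^2)
  }, 1)
  t_star <- seq(-pi / 2, pi / 2, by = 1e-4)[which.min(obj)]
  oracle <- (u %*% rot2(-t_star / 2) + refl %*% rot2(t_star / 2)) / 2
  got <- symmetrize(cfg, map)
  got_u <- sweep(got, 2, colMeans(got)) / centroid_size(cfg)
  # grid resolution 1e-4 rad limits agreement to ~1e-4
  expect_equal(got_u, oracle, tolerance = 1e-3)
})

test_that("face space PCA recovers structure and round-trips scores", {
  # rank-1 population: PC1 = +/- direction, explained ratio 1
  set.seed(51)
  base <- center_and_scale(matrix(rnorm(16), ncol = 2))
  v <- rnorm(16); v <- v / sqrt(sum(v^2))
  pop1 <- lapply(seq(-1, 1, length.out = 9), function(t) {
    base + matrix(t * 0.05 * v, ncol = 2, byrow = TRUE)
  })
  fs1 <- fit_face_space(pop1, 1)
  expect_equal(fs1$explained_ratio[1], 1, tolerance = 1e-9)
  expect_equal(abs(sum(fs1$loadings[, 1] * v)), 1, tolerance = 1e-9)
  expect_error(fit_face_space(pop1, 3), "rank")

  # 80 landmarks flatten to 160 coordinates
  pop80 <- generate_shape_population(n_faces = 40, n_landmarks = 80,
                                     transform_jitter = FALSE, seed = 7)
  fs80 <- fit_face_space(pop80, 3)
  expect_identical(nrow(fs80$loadings), 160L)
  expect_true(all(diff(fs80$explained_ratio) <= 1e-12))
  expect_lte(sum(fs80$explained_ratio), 1 + 1e-12)
  # loadings orthonormal
  expect_equal(crossprod(fs80$loadings), diag(3), tolerance = 1e-9)

  # round trip: scores -> landmarks -> scores
  sc <- c(1.3, -0.7, 0.4)
  shape <- scores_to_landmarks(fs80, sc)
  expect_equal(landmarks_to_scores(fs80, shape), sc, tolerance = 1e-10)
  expect_equal(scores_to_landmarks(fs80, c(0, 0, 0)), fs80$mean_shape)
  # linearity: +2 and -2 are reflections about the mean shape
  d_plus <- scores_to_landmarks(fs80, c(2, 0, 0)) - fs80$mean_shape
  d_minus <- scores_to_landmarks(fs80, c(-2, 0, 0)) - fs80$mean_shape
  expect_equal(d_plus, -d_minus, tolerance = 1e-12)
})

test_that("full-rank PCA reconstructs exactly; ratios sum to one", {
  set.seed(61)
  pop <- generate_shape_population(n_faces = 9, n_landmarks = 12,
                                   factor_sds = c(0.05, 0.03),
                                   noise_sd = 0.01, transform_jitter = FALSE,
                                   seed = 9)
  n <- length(pop)
  fs <- fit_face_space(pop, n - 1)  # full achievable rank
  expect_equal(sum(fs$explained_ratio), 1, tolerance = 1e-9)
  for (i in c(1, 5)) {
    sc <- landmarks_to_scores(fs, pop[[i]])
    expect_lt(max(abs(scores_to_landmarks(fs, sc) - pop[[i]])), 1e-9)
  }
})

test_that("symmetrized population has zero asymmetric variance", {
  pop <- generate_shape_population(n_faces = 25, n_landmarks = 16,
                                   noise_sd = 0.01, seed = 13)
  map <- attr(pop, "map")
  g <- gpa_align(pop)
  asym <- vapply(seq_len(dim(g$aligned)[3]), function(i) {
    asymmetry_score(symmetrize(g$aligned[, , i], map), map)
  }, 1)
  expect_lt(max(asym), 1e-9)
})
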