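test_that("scenario validation lists offending fields", {
  expect_s3_class(cluster_scenario(), "cluster_scenario")
  expect_error(cluster_scenario(overlap_fraction = 1.2), "overlap_fraction")
  expect_error(cluster_scenario(n_frames = 20, division_frame = 20),
               "division_frame")
  expect_error(cluster_scenario(d_nuc = -1, noise_sigma = -2),
               "d_nuc.*noise_sigma")
})

test_that("zero-noise frames equal the rendered truth exactly", {
  sc <- cluster_scenario(n_frames = 4L, noise_sigma = 0, seed = 301)
  sim <- simulate_cluster_video(sc)
  for (t in 1:4)
    expect_equal(sim$stack[, , t],
                 render_mixture(sim$truth$params[[t]], sc$frame_shape))
})

test_that("the truth nucleus count switches at the division frame", {
  sc <- cluster_scenario(n_frames = 12L, division_frame = 7L, seed = 302)
  sim <- simulate_cluster_video(sc)
  counts <- vapply(sim$truth$params, length, integer(1))
  expect_equal(counts, c(rep(2L, 6), rep(3L, 6)))
  expect_equal(sim$truth$division_frame, 7L)
  expect_equal(sqrt(sum(sim$truth$mother_axis^2)), 1)
  # daughters are born at the programmed separation along the programmed angle
  dg <- sim$truth$params[[7]][2:3]
  dvec <- dg[[1]]$mu - dg[[2]]$mu
  expect_equal(sqrt(sum(dvec^2)), (1 - sc$overlap_fraction) * sc$d_nuc,
               tolerance = 1e-9)
  ang <- acos(abs(sum(dvec / sqrt(sum(dvec^2)) * sim$truth$mother_axis))) * 180 / pi
  expect_equal(ang, sc$division_angle, tolerance = 1e-6)
  # daughters start at half the adult area
  expect_equal(det(dg[[1]]$S), nucleus_priors(sc$d_nuc, sc$w_nuc)$A_nuc / 2,
               tolerance = 1e-9)
})

test_that("generation is bitwise reproducible and seed-sensitive", {
  sc <- cluster_scenario(n_frames = 5L, division_frame = 3L, seed = 303)
  a <- simulate_cluster_video(sc)
  b <- simulate_cluster_video(sc)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$params, b$truth$params)
  sc2 <- cluster_scenario(n_frames = 5L, division_frame = 3L, seed = 304)
  expect_false(identical(simulate_cluster_video(sc2)$stack, a$stack))
})

test_that("background noise has the prescribed variance", {
  sc <- cluster_scenario(n_frames = 2L, frame_shape = c(80L, 80L),
                         noise_sigma = 0.08, seed = 305)
  sim <- simulate_cluster_video(sc)
  corner <- as.numeric(sim$stack[1:12, 1:12, 1])   # far from both nuclei
  # the zero background is clipped at 0, so pixels follow max(N(0, s), 0)
  # whose variance is s^2 * (1/2 - 1/(2*pi))
  v_expected <- 0.08^2 * (1 / 2 - 1 / (2 * pi))
  expect_equal(var(corner), v_expected, tolerance = 0.25)
})

test_that("fitting the true order recovers the generating parameters", {
  sc <- cluster_scenario(n_frames = 2L, noise_sigma = 0, seed = 306)
  sim <- simulate_cluster_video(sc)
  pr <- nucleus_priors(sc$d_nuc, sc$w_nuc)
  img <- sim$stack[, , 1]
  dmap <- build_distance_map(estimate_foreground(img, pr))
  ft <- fit_frame(img, init_first_frame(img, 2, pr), dmap, pr)
  truth <- mixture_params(sim$truth$params[[1]])
  idx <- match_components(ft$params, truth)
  expect_equal(sort(idx), 1:2)
  for (k in 1:2)
    expect_lt(sqrt(sum((ft$params$components[[k]]$mu -
                        truth$components[[idx[k]]]$mu)^2)), 0.2)
})

test_that("pattern fields embed clusters and record their layout", {
  pf <- simulate_pattern_field(field_shape = c(220L, 220L),
                               pattern_diameter = 20, n_frames = 2L,
                               cluster_fraction = 0.5, seed = 307)
  expect_gt(nrow(pf$centers), 3)
  expect_true(all(dim(pf$pattern_image) == c(220, 220)))
  expect_equal(dim(pf$stack)[3], 2L)
  # embedded cluster pixels equal the standalone cluster inside its window
  j <- pf$cluster_centers$index[1]
  w <- attr(pf, "window")
  w <- if (is.null(w)) round(1.5 * 20) else w
  cx <- round(pf$cluster_centers$x[1]); cy <- round(pf$cluster_centers$y[1])
  sub <- pf$stack[(cy - w):(cy + w) + 1, (cx - w):(cx + w) + 1, 1]
  expect_equal(sub, pf$clusters[[as.character(j)]]$stack[, , 1])
})

test_that("defocus frames blur and dim one nucleus", {
  sc <- cluster_scenario(n_frames = 3L, noise_sigma = 0,
                         defocus_frames = 2L, seed = 308)
  sim <- simulate_cluster_video(sc)
  w_normal <- sim$truth$params[[1]][[1]]$w
  w_defocus <- sim$truth$params[[2]][[1]]$w
  expect_equal(w_defocus, 0.7 * w_normal)
  expect_gt(det(sim$truth$params[[2]][[1]]$S),
            det(sim$truth$params[[1]][[1]]$S))
})
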