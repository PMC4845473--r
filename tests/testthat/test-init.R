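pr_init <- nucleus_priors(10, 0.5)

two_cell_frame <- function(centers = list(c(20, 30), c(40, 30))) {
  render_mixture(lapply(centers, function(mu)
    gaussian_component(pr_init$w_nuc, mu, diag(2) * pr_init$sigma_nuc^2)),
    c(60, 60))
}

test_that("first-frame initialization uses seeds, priors and random padding", {
  img <- two_cell_frame()
  p2 <- init_first_frame(img, 2, pr_init)
  ctrs <- t(vapply(p2$components, `[[`, numeric(2), "mu"))
  expect_equal(nrow(ctrs), 2L)
  d <- apply(ctrs, 1, function(mu)
    min(sqrt((mu[1] - c(20, 40))^2 + (mu[2] - 30)^2)))
  expect_true(all(d < 1.5))
  # every intensity starts at the prior; covariance isotropic with the
  # determinant at the area prior
  expect_true(all(vapply(p2$components, `[[`, numeric(1), "w") == pr_init$w_nuc))
  expect_equal(p2$components[[1]]$S, diag(2) * sqrt(pr_init$A_nuc))
  expect_equal(det(p2$components[[1]]$S), pr_init$A_nuc)
  # K = 3 on a two-seed frame: third center is a reproducible random
  # foreground location
  set.seed(5); p3a <- init_first_frame(img, 3, pr_init)
  set.seed(5); p3b <- init_first_frame(img, 3, pr_init)
  expect_identical(p3a, p3b)
  fg <- estimate_foreground(img, pr_init)
  mu3 <- p3a$components[[3]]$mu
  expect_true(fg[round(mu3[2]) + 1, round(mu3[1]) + 1])
  expect_error(init_first_frame(matrix(0, 30, 30), 2, pr_init), "no cells")
})

test_that("bootstrap sigma initialization estimates shapes from the frame", {
  set.seed(77)
  tr <- mixture_params(list(
    gaussian_component(0.5, c(18, 30), rotate_covariance(diag(c(14, 6)), 25)),
    gaussian_component(0.5, c(42, 30), rotate_covariance(diag(c(14, 6)), -40))))
  img <- render_mixture(tr, c(60, 60))
  p <- init_first_frame(img, 2, pr_init, sigma_init = "bootstrap", n_boot = 3)
  for (k in 1:2) {
    S <- p$components[[k]]$S
    # a valid, data-scaled shape prior: positive definite with the
    # determinant near the area prior (entry-wise medians average the
    # orientations of the restart fits away, so no anisotropy is implied)
    expect_gt(det(S), 0)
    expect_equal(S[1, 2], S[2, 1])
    expect_equal(det(S), pr_init$A_nuc, tolerance = 0.2)
    expect_false(identical(S, diag(2) * sqrt(pr_init$A_nuc)))
  }
  # centers still come from the seeds, as in the default mode
  p0 <- init_first_frame(img, 2, pr_init)
  expect_equal(lapply(p$components, `[[`, "mu"),
               lapply(p0$components, `[[`, "mu"))
})

test_that("frame-to-frame initialization moves halfway to the closest maximum", {
  img <- two_cell_frame()
  seeds <- detect_seeds(img, pr_init)
  prev <- mixture_params(list(
    gaussian_component(0.4, c(14, 30), diag(2) * pr_init$sigma_nuc^2),
    gaussian_component(0.4, c(46, 30), diag(2) * pr_init$sigma_nuc^2)))
  init <- init_next_frame(prev, img, pr_init, seeds = seeds)
  # seeds sit at the blob centers (20,30) and (40,30): midpoint rule
  expect_equal(init$components[[1]]$mu, c((14 + seeds$x[seeds$x < 30]) / 2, 30),
               tolerance = 0.5)
  # intensity: halfway between previous w and the image at the maximum
  j <- which(seeds$x > 30)[1]                    # the seed nearest component 2
  expect_equal(init$components[[2]]$w,
               (0.4 + img[seeds$y[j] + 1, seeds$x[j] + 1]) / 2,
               tolerance = 1e-6)
  # with no maxima, parameters carry over unchanged
  none <- seeds[0, ]
  init2 <- init_next_frame(prev, img, pr_init, seeds = none)
  expect_equal(init2$components[[1]]$mu, c(14, 30))
  expect_equal(init2$components[[1]]$w, 0.4)
})

test_that("covariance initialization extrapolates the rotation", {
  img <- two_cell_frame()
  seeds <- detect_seeds(img, pr_init)
  S0 <- rotate_covariance(diag(c(16, 4)), 30)
  prev <- mixture_params(list(
    gaussian_component(0.5, c(20, 30), S0),
    gaussian_component(0.5, c(40, 30), S0)))
  # constant orientation history: delta = 0, covariance unchanged
  th <- vapply(prev$components, function(cp) covariance_eigen(cp$S)$theta,
               numeric(1))
  init <- init_next_frame(prev, img, pr_init, prev_theta = th, seeds = seeds)
  expect_equal(init$components[[1]]$S, S0, tolerance = 1e-9)
  # 10-degree-per-frame history: covariance rotated 10 degrees further
  init2 <- init_next_frame(prev, img, pr_init, prev_theta = th - 10,
                           seeds = seeds)
  expect_equal(init2$components[[1]]$S, rotate_covariance(S0, 10),
               tolerance = 1e-9)
  # no history: unrotated
  init3 <- init_next_frame(prev, img, pr_init, seeds = seeds)
  expect_equal(init3$components[[1]]$S, S0)
})
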