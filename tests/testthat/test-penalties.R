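test_that("build_distance_map is the exact Euclidean transform of the complement", {
  m <- matrix(TRUE, 6, 6)
  expect_true(all(build_distance_map(m) == 0))
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE       # foreground pixel (x=0, y=0)
  D <- build_distance_map(m)
  expect_equal(D[5, 4], 5)                        # pixel (x=3, y=4): 3-4-5
  expect_equal(D[1, 1], 0)
  set.seed(41)
  mk <- matrix(runif(100) < 0.2, 10, 10)
  if (!any(mk)) mk[3, 3] <- TRUE
  expect_equal(unclass(build_distance_map(mk))[, ], oracle_distance_map(mk),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(build_distance_map(matrix(FALSE, 4, 4)), "empty foreground")
})

make_params <- function(centers, w = 1, S = diag(2)) {
  mixture_params(lapply(centers, function(mu) gaussian_component(w, mu, S)))
}

test_that("location_penalty sums squared distances at component centers", {
  m <- matrix(FALSE, 12, 12); m[4:8, 4:8] <- TRUE   # foreground block
  D <- build_distance_map(m)
  on_fg <- make_params(list(c(4, 4), c(6, 6)))
  expect_equal(location_penalty(on_fg, D), 0)
  # one center 3 px left of the block edge (x=0, y=5): distance 3
  p <- make_params(list(c(0, 5), c(5, 5)))
  expect_equal(location_penalty(p, D), 9)
  # centers at distances 3 and 4
  p <- make_params(list(c(0, 5), c(5, 11)), S = diag(2))
  expect_equal(location_penalty(p, D), 9 + 16)
  # out-of-image center: border distance plus overshoot
  p2 <- make_params(list(c(-2, 5), c(5, 5)))
  expect_equal(location_penalty(p2, D),
               (unclass(D)[6, 1] + 2)^2)
})

test_that("area and intensity penalties are squared deviations from the priors", {
  pr <- nucleus_priors(d_nuc = sqrt(4 * 20 / pi), w_nuc = 10)  # A_nuc = 20
  expect_equal(pr$A_nuc, 20)
  exact <- make_params(list(c(0, 0), c(5, 5)), w = 10,
                       S = diag(c(5, 4)))                      # det 20
  expect_equal(area_penalty(exact, pr), 0)
  expect_equal(intensity_penalty(exact, pr), 0)
  p <- make_params(list(c(0, 0), c(5, 5)), w = 10, S = diag(c(6, 4)))  # det 24
  expect_equal(area_penalty(p, pr), 2 * 16)
  p <- mixture_params(list(
    gaussian_component(10, c(0, 0), diag(c(5, 4))),
    gaussian_component(10, c(3, 3), diag(c(5, 4))),
    gaussian_component(13, c(6, 6), diag(c(5, 4)))))
  expect_equal(intensity_penalty(p, pr), 9)
  # quadratic form: doubling every deviation quadruples the penalty
  p2 <- mixture_params(list(
    gaussian_component(10, c(0, 0), diag(c(5, 4))),
    gaussian_component(10, c(3, 3), diag(c(5, 4))),
    gaussian_component(16, c(6, 6), diag(c(5, 4)))))
  expect_equal(intensity_penalty(p2, pr), 4 * intensity_penalty(p, pr))
})

test_that("global_error multiplies the residual by one plus the penalties", {
  set.seed(51)
  pr <- nucleus_priors(6, 1)
  params <- random_mixture(2, c(20, 20), pr)
  frame <- render_mixture(params, c(20, 20))
  D <- build_distance_map(matrix(TRUE, 20, 20))   # all foreground: f_loc = 0
  g <- global_error(frame, params, D, pr)
  comp <- attr(g, "components")
  expect_equal(as.numeric(g),
               comp["f_err"] * (1 + comp["f_loc"] + comp["f_vol"] + comp["f_int"]),
               ignore_attr = TRUE)
  # exact render: f_err == 0 makes f_global == 0 whatever the penalties
  expect_equal(comp[["f_err"]], 0, tolerance = 1e-20)
  expect_equal(as.numeric(g), 0, tolerance = 1e-20)
  # direct substitution with synthetic penalty values
  noisy <- frame + 1
  g2 <- attr(global_error(noisy, params, D, pr), "components")
  expect_equal(g2[["f_err"]], 400)   # constant difference 1 over 400 px
})

test_that("penalties vanish exactly at the priors and are non-negative", {
  set.seed(61)
  pr <- nucleus_priors(8, 0.7)
  for (i in 1:10) {
    params <- random_mixture(2, c(30, 30), pr)
    D <- build_distance_map(matrix(TRUE, 30, 30))
    expect_gte(location_penalty(params, D), 0)
    expect_gte(area_penalty(params, pr), 0)
    expect_gte(intensity_penalty(params, pr), 0)
  }
  at_prior <- make_params(list(c(3, 3), c(10, 10)), w = pr$w_nuc,
                          S = diag(2) * sqrt(pr$A_nuc))
  expect_equal(area_penalty(at_prior, pr), 0)
  expect_equal(intensity_penalty(at_prior, pr), 0)
})

test_that("C++ objective agrees with the R implementation", {
  set.seed(71)
  pr <- nucleus_priors(10, 0.5)
  for (i in 1:5) {
    params <- random_mixture(sample(2:3, 1), c(40, 40), pr)
    frame <- render_mixture(params, c(40, 40)) +
      matrix(rnorm(1600, 0, 0.05), 40, 40)
    fg <- estimate_foreground(frame, pr)
    D <- build_distance_map(fg)
    fR <- as.numeric(global_error(frame, params, D, pr))
    fC <- mitodiv:::cpp_global_error(frame, mitodiv:::pack_params(params),
                                     unclass(D), pr$A_nuc, pr$w_nuc)
    expect_equal(fR, fC, tolerance = 1e-12, ignore_attr = TRUE)
  }
})
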