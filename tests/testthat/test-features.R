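# Lightweight stand-in sequence fits built directly from parameters, so
# feature computations can be tested against hand-computable values.
fake_fit <- function(centers3_by_frame, f2 = NULL, f3 = NULL, stack = NULL) {
  n <- length(centers3_by_frame)
  mk_fit <- function(K, mus, ferr) {
    params <- mixture_params(lapply(mus, function(mu)
      gaussian_component(1, mu, diag(2) * 4)))
    structure(list(frame_index = NA, K = K, params = params, f_err = ferr,
                   f_global = ferr, theta = rep(0, K), converged = TRUE),
              class = "frame_fit")
  }
  if (is.null(stack))
    stack <- lapply(seq_len(n), function(i) matrix(0.5, 40, 40))
  structure(list(
    fits2 = lapply(seq_len(n), function(t)
      mk_fit(2, list(c(5, 5), c(20, 20)), if (is.null(f2)) 1 else f2[t])),
    fits3 = lapply(seq_len(n), function(t)
      mk_fit(3, centers3_by_frame[[t]], if (is.null(f3)) 1 else f3[t])),
    priors = nucleus_priors(10, 0.5), stack = stack, n_frames = n),
    class = "nuclei_gmm")
}

test_that("F1 is the elementwise residual ratio with a guarded zero", {
  ctrs <- rep(list(list(c(0, 0), c(3, 4), c(10, 10))), 3)
  fit <- fake_fit(ctrs, f2 = c(2, 2, 4), f3 = c(1, 1, 4))
  expect_equal(feature_f1(fit), c(0.5, 0.5, 1))
  fit0 <- fake_fit(ctrs, f2 = c(0, 2, 4), f3 = c(1, 1, 4))
  F1 <- feature_f1(fit0)
  expect_equal(F1[1], 1)             # perfect 2-fit: models tie
  expect_equal(attr(F1, "flagged"), 1L)
})

test_that("F2 is the minimum pairwise center distance", {
  ctrs <- list(list(c(0, 0), c(3, 4), c(10, 10)))
  expect_equal(feature_f2(fake_fit(ctrs)), 5)
  # coincident centers give zero
  ctrs2 <- list(list(c(2, 2), c(2, 2), c(10, 10)))
  expect_equal(feature_f2(fake_fit(ctrs2)), 0)
  # translation invariance
  shift <- list(list(c(7, 1), c(10, 5), c(17, 11)))
  expect_equal(feature_f2(fake_fit(shift)), 5)
})

test_that("F3 is the population variance sampled between the closest centers", {
  # constant image: zero variance
  ctrs <- list(list(c(2, 10), c(11, 10), c(30, 30)))
  expect_equal(feature_f3(fake_fit(ctrs)), 0)
  # half-zero / half-one step along the sampled segment: variance 1/4
  img <- matrix(0, 40, 40); img[, 26:40] <- 1   # columns x >= 25 are 1
  ctrs <- list(list(c(20, 10), c(29, 10), c(35, 35)))
  # closest pair spans x in [20, 29]: 10 integer samples, 5 below the step
  fit <- fake_fit(ctrs, stack = list(img))
  expect_equal(feature_f3(fit), 0.25)
  # coincident centers: defined as zero
  ctrs0 <- list(list(c(5, 5), c(5, 5), c(30, 30)))
  expect_equal(feature_f3(fake_fit(ctrs0, stack = list(img))), 0)
})

test_that("segment inside one nucleus has low F3, across background high F3", {
  pr <- nucleus_priors(10, 1)
  blobs <- list(gaussian_component(1, c(15, 20), diag(2) * pr$sigma_nuc^2),
                gaussian_component(1, c(40, 20), diag(2) * pr$sigma_nuc^2))
  img <- render_mixture(blobs, c(60, 60))
  inside <- list(list(c(13, 20), c(17, 20), c(40, 20)))
  across <- list(list(c(15, 20), c(40, 20), c(55, 55)))
  f_in <- feature_f3(fake_fit(inside, stack = list(img)))
  f_across <- feature_f3(fake_fit(across, stack = list(img)))
  expect_lt(f_in, 0.01)
  expect_gt(f_across, 10 * f_in)
})

test_that("the derivative product fires only on the full signature", {
  n <- 20
  flat <- rep(1, n)
  expect_equal(derivative_product(flat, flat, flat), rep(0, n - 1))
  # simultaneous jumps: F1 down, F2 and F3 up at frame 11
  F1 <- c(rep(1, 10), rep(0.6, 10))
  F2 <- c(rep(2, 10), rep(8, 10))
  F3 <- c(rep(0.1, 10), rep(0.5, 10))
  P <- derivative_product(F1, F2, F3)
  expect_equal(which(P > 0), 10L)    # aligned to the later frame (11) at index 10
  # an upward step in only two features yields zero everywhere
  P2 <- derivative_product(flat, F2, F3)
  expect_equal(P2, rep(0, n - 1))
  # F1 *rising* (wrong direction) contributes nothing
  P3 <- derivative_product(rev(F1), F2, F3)
  expect_equal(P3, rep(0, n - 1))
})

test_that("detect_transition calls the earliest significant peak", {
  base <- rep(0, 40)
  expect_match(detect_transition(base)$excluded_reason, "no significant peak")
  one <- base; one[20] <- 100
  ev <- detect_transition(one)
  expect_equal(ev$event_frame, 21L)  # product index 20 = frame 21
  two <- base; two[15] <- 80; two[30] <- 300
  expect_equal(detect_transition(two)$event_frame, 16L)
  # invariant to positive rescaling of P
  expect_equal(detect_transition(one * 37)$event_frame, 21L)
  # small chance coincidences below the absolute floor do not qualify
  noise <- base; noise[c(5, 12, 33)] <- c(0.4, 0.9, 0.6)
  expect_match(detect_transition(noise)$excluded_reason, "no significant peak")
})

test_that("compute_features aligns derivatives to the later frame", {
  ctrs <- rep(list(list(c(0, 0), c(3, 4), c(10, 10))), 6)
  fit <- fake_fit(ctrs, f2 = rep(2, 6), f3 = c(1, 1, 1, 2, 2, 2))
  fs <- compute_features(fit)
  expect_s3_class(fs, "feature_series")
  expect_equal(fs$frame, 1:6)
  expect_true(is.na(fs$dF1[1]) && is.na(fs$P[1]))
  expect_equal(fs$dF1[4], 0.5)       # F1 jumps between frames 3 and 4
})
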