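test_that("illumination correction flattens a ramp over identical blobs", {
  pr <- nucleus_priors(12, 1)
  blobs <- lapply(list(c(30, 30), c(90, 30), c(150, 30),
                       c(30, 90), c(90, 90), c(150, 90)), function(mu)
    gaussian_component(1, mu, diag(2) * 16))
  img <- render_mixture(blobs, c(120, 180))
  ramp <- outer(rep(1, 120), seq(0.5, 1, length.out = 180))   # 2x ramp
  shaded <- img * ramp
  corr <- correct_illumination(shaded)
  expect_true(all(corr >= 0 & corr <= 1))
  peaks <- vapply(blobs, function(b) corr[b$mu[2] + 1, b$mu[1] + 1], numeric(1))
  expect_lt((max(peaks) - min(peaks)) / max(peaks), 0.10)
  # before correction the ramp spreads the peaks about twofold
  raw_peaks <- vapply(blobs, function(b) shaded[b$mu[2] + 1, b$mu[1] + 1],
                      numeric(1))
  expect_gt((max(raw_peaks) - min(raw_peaks)) / max(raw_peaks), 0.3)
  # constant image passes through unchanged
  expect_equal(correct_illumination(matrix(0.4, 32, 32)),
               matrix(0.4, 32, 32))
})

test_that("locate_patterns finds all non-border disks on a shaded honeycomb", {
  pf <- simulate_pattern_field(field_shape = c(260L, 260L),
                               pattern_diameter = 20, ramp_factor = 2,
                               n_frames = 1L, cluster_fraction = 0,
                               seed = 401)
  corr <- correct_illumination(pf$pattern_image)
  lay <- locate_patterns(corr, 20)
  expect_equal(nrow(lay), nrow(pf$centers))
  for (j in seq_len(nrow(pf$centers))) {
    d <- sqrt((lay$x - pf$centers$x[j])^2 + (lay$y - pf$centers$y[j])^2)
    expect_lt(min(d), 2)
  }
  # blank image: empty layout
  expect_equal(nrow(locate_patterns(matrix(0, 100, 100), 20)), 0L)
})

test_that("disks too close to the border are excluded", {
  img <- matrix(0, 100, 100)
  xs <- seq_len(100) - 1
  disk <- function(cx, cy) 1 / (1 + exp(2 * (sqrt(outer((xs - cy)^2,
                                                        (xs - cx)^2, "+")) - 8)))
  img <- disk(50, 50) + disk(10, 50)       # second disk near the left border
  lay <- locate_patterns(img, 16, window = 24)
  expect_equal(nrow(lay), 1L)
  expect_lt(abs(lay$x - 50), 2)
})

test_that("cropping is pixel-exact and round-trips", {
  set.seed(402)
  stack <- array(runif(100 * 100 * 2), c(100, 100, 2))
  layout <- data.frame(x = c(40, 70), y = c(35, 60))
  cr <- crop_sequences(stack, layout, window = 20)
  expect_length(cr$stacks, 2L)
  expect_equal(dim(cr$stacks[[1]]), c(41, 41, 2))
  # pixel identity at the window corner
  expect_equal(cr$stacks[[1]][1, 1, 1], stack[35 - 20 + 1, 40 - 20 + 1, 1])
  # round trip: pasting back reproduces the original pixels
  recon <- array(NA_real_, dim(stack))
  for (j in 1:2) {
    cx <- cr$index$cx[j]; cy <- cr$index$cy[j]
    recon[(cy - 20):(cy + 20) + 1, (cx - 20):(cx + 20) + 1, ] <- cr$stacks[[j]]
  }
  inside <- !is.na(recon)
  expect_identical(recon[inside], stack[inside])
  # windows crossing the border are dropped; empty layouts give empty lists
  cr2 <- crop_sequences(stack, data.frame(x = 5, y = 50), window = 20)
  expect_length(cr2$stacks, 0L)
  expect_length(crop_sequences(stack, data.frame(x = numeric(0),
                                                 y = numeric(0)),
                               window = 20)$stacks, 0L)
})

test_that("pre-screening flags empty and overcrowded first frames", {
  pr <- nucleus_priors(10, 0.5)
  expect_equal(prescreen_sequence(array(0.1, c(60, 60, 2)), pr), "no cells")
  sc <- cluster_scenario(n_frames = 2L, seed = 403)
  sim <- simulate_cluster_video(sc)
  expect_null(prescreen_sequence(sim$stack, pr))
  crowded <- render_mixture(lapply(list(c(10, 10), c(30, 10), c(50, 10),
                                        c(10, 40), c(30, 40), c(50, 40)),
                                   function(mu)
    gaussian_component(0.5, mu, diag(2) * pr$sigma_nuc^2)), c(60, 60))
  expect_equal(prescreen_sequence(array(crowded, c(60, 60, 1)), pr),
               "too many cells at start")
})

test_that("TIFF round trip preserves stacks to sample precision", {
  sc <- cluster_scenario(n_frames = 3L, seed = 404)
  sim <- simulate_cluster_video(sc)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_equal(dim(back), dim(sim$stack))
  expect_lt(max(abs(back - pmin(pmax(sim$stack, 0), 1))), 1.1 / 65535)
})
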