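# Independent brute-force oracles used to validate the fast implementations.

# Per-pixel loop evaluation of the mixture image (no vectorization, no
# truncation): the definitional form of the model.
oracle_render <- function(params, shape) {
  comps <- if (inherits(params, "mixture_params")) params$components else params
  out <- matrix(0, shape[1], shape[2])
  for (row in seq_len(shape[1])) {
    for (col in seq_len(shape[2])) {
      x <- col - 1; y <- row - 1
      v <- 0
      for (cp in comps) {
        d <- c(x, y) - cp$mu
        v <- v + cp$w * exp(-0.5 * drop(t(d) %*% solve(cp$S) %*% d))
      }
      out[row, col] <- v
    }
  }
  out
}

# Brute-force nearest-foreground distance for every pixel.
oracle_distance_map <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (row in seq_len(nrow(mask))) {
    for (col in seq_len(ncol(mask))) {
      out[row, col] <- sqrt(min((fg[, 1] - row)^2 + (fg[, 2] - col)^2))
    }
  }
  out
}

# Direct two-sample maximum-ECDF-gap statistic.
oracle_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# Greedy matching of fitted components to truth components by center
# distance; returns the truth index for each fitted component.
match_components <- function(fitted, truth) {
  fc <- if (inherits(fitted, "mixture_params")) fitted$components else fitted
  tc <- if (inherits(truth, "mixture_params")) truth$components else truth
  vapply(fc, function(cp) {
    which.min(vapply(tc, function(t2) sum((cp$mu - t2$mu)^2), numeric(1)))
  }, integer(1))
}

random_spd <- function() {
  l1 <- runif(1, 2, 30)
  l2 <- runif(1, 1, l1)
  th <- runif(1, -90, 90)
  rotate_covariance(diag(c(l1, l2)), th)
}
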