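# Bilinear interpolation at continuous 0-based (x, y), clamped to the image.
bilinear_sample <- function(frame, x, y) {
  nr <- nrow(frame); nc <- ncol(frame)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 2); y1 <- y0 + 1
  if (nc == 1L) { x0 <- x1 <- 0 }
  if (nr == 1L) { y0 <- y1 <- 0 }
  fx <- x - x0; fy <- y - y0
  v00 <- frame[cbind(y0 + 1, x0 + 1)]
  v01 <- frame[cbind(y0 + 1, x1 + 1)]
  v10 <- frame[cbind(y1 + 1, x0 + 1)]
  v11 <- frame[cbind(y1 + 1, x1 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Fitting-error ratio feature (F1)
#'
#' Per-frame ratio of the raw residual of the 3-component fit to that of
#' the 2-component fit.  While the cluster truly holds two cells the extra
#' component only refines the fit and the ratio sits close to (just below)
#' one; on the frame where a third cell appears the 2-component model
#' breaks down and the ratio drops sharply.
#'
#' @param fit a [fit_nuclei()] result.
#' @return numeric vector, one value per frame.  Frames with a perfect
#'   2-component fit (`f2 == 0`) get `F1 = 1` (the models tie) and are
#'   reported in attribute `"flagged"`.
#' @export
feature_f1 <- function(fit) {
  r <- residuals(fit)
  flagged <- which(r[, "f2"] == 0)
  out <- as.numeric(ifelse(r[, "f2"] == 0, 1, r[, "f3"] / r[, "f2"]))
  if (length(flagged)) attr(out, "flagged") <- flagged
  out
}

#' Closest-centers distance feature (F2)
#'
#' Per-frame minimum pairwise Euclidean distance among the three component
#' centers of the 3-component fit.  Modelling two cells with three
#' components forces two centers onto one nucleus (small F2); once three
#' cells exist each component takes one cell and F2 jumps up.
#'
#' @inheritParams feature_f1
#' @return numeric vector, one value per frame.
#' @export
feature_f2 <- function(fit) {
  vapply(fit$fits3, function(ft) {
    mus <- lapply(ft$params$components, `[[`, "mu")
    min(sqrt((mus[[1]][1] - mus[[2]][1])^2 + (mus[[1]][2] - mus[[2]][2])^2),
        sqrt((mus[[1]][1] - mus[[3]][1])^2 + (mus[[1]][2] - mus[[3]][2])^2),
        sqrt((mus[[2]][1] - mus[[3]][1])^2 + (mus[[2]][2] - mus[[3]][2])^2))
  }, numeric(1))
}

#' Inter-center intensity variance feature (F3)
#'
#' Per-frame variance of the image intensity sampled along the straight
#' segment joining the two closest centers of the 3-component fit
#' (about one sample per pixel, bilinear interpolation, population
#' variance).  Low variance means the segment stays inside one bright
#' nucleus (both components share a cell); high variance means background
#' lies between the two centers, i.e. they model distinct cells.
#'
#' @inheritParams feature_f1
#' @param stack image stack; defaults to the one stored in the fit.
#' @return numeric vector, one value per frame.
#' @export
feature_f3 <- function(fit, stack = NULL) {
  frames <- if (is.null(stack)) fit$stack else as_frame_list(stack)
  vapply(seq_along(fit$fits3), function(t) {
    ft <- fit$fits3[[t]]
    mus <- lapply(ft$params$components, `[[`, "mu")
    pr <- list(c(1, 2), c(1, 3), c(2, 3))
    dd <- vapply(pr, function(ij)
      sqrt(sum((mus[[ij[1]]] - mus[[ij[2]]])^2)), numeric(1))
    ij <- pr[[which.min(dd)]]
    a <- mus[[ij[1]]]; b <- mus[[ij[2]]]
    len <- dd[which.min(dd)]
    if (len == 0) return(0)
    u <- seq(0, 1, length.out = ceiling(len) + 1)
    v <- bilinear_sample(frames[[t]], a[1] + u * (b[1] - a[1]),
                         a[2] + u * (b[2] - a[2]))
    mean((v - mean(v))^2)
  }, numeric(1))
}

# Robust scale used to normalize feature derivatives; falls back to the
# standard deviation when more than half the values coincide (MAD = 0).
robust_scale <- function(x) {
  s <- stats::mad(x)
  if (is.finite(s) && s > 0) return(s)
  s <- stats::sd(x)
  if (is.finite(s) && s > 0) return(s)
  1
}

#' Product of the normalized feature derivatives
#'
#' Forward differences of the three features, each normalized by its own
#' robust scale (median absolute deviation) so that the incommensurate
#' units of F1 (ratio), F2 (pixels) and F3 (squared intensity) carry equal
#' weight.  The two-to-three-cell transition drives F2 and F3 up and F1
#' down, so the product multiplies the positive parts of dF2 and dF3 with
#' the positive part of -dF1; any frame lacking the full signature yields
#' zero.
#'
#' The intensity-variance factor is allowed to lag one frame: daughters
#' born at strong overlap leave no dark gap between their centers until
#' they have separated for a frame, so the F3 rise can trail the error
#' and geometry jumps.  Each frame's F3 factor is therefore the larger of
#' its own and the following frame's normalized increase; the F1 and F2
#' factors stay strictly frame-aligned and fix the event timing.
#'
#' @param F1,F2,F3 per-frame feature vectors of equal length.
#' @param f3_lag number of frames the F3 confirmation may trail (0
#'   disables the lookahead).
#' @return numeric vector of length `length(F1) - 1`, aligned to the later
#'   frame of each difference.
#' @export
derivative_product <- function(F1, F2, F3, f3_lag = 1L) {
  stopifnot(length(F1) == length(F2), length(F2) == length(F3),
            length(F1) >= 2L)
  d1 <- diff(F1); d2 <- diff(F2); d3 <- diff(F3)
  z1 <- pmax(-d1 / robust_scale(d1), 0)
  z2 <- pmax(d2 / robust_scale(d2), 0)
  z3 <- pmax(d3 / robust_scale(d3), 0)
  if (f3_lag > 0L) {
    for (l in seq_len(f3_lag))
      z3 <- pmax(z3, c(z3[-seq_len(l)], rep(0, l)))
  }
  z1 * z2 * z3
}

#' Time features of a sequence fit
#'
#' Computes the three transition features, their forward differences and
#' the normalized derivative product for every frame of a fitted sequence.
#'
#' @inheritParams feature_f3
#' @return a data frame of class `"feature_series"` with columns `frame`,
#'   `F1`, `F2`, `F3`, `dF1`, `dF2`, `dF3` and `P` (differences and product
#'   are `NA` on the first frame and aligned to the later frame).
#' @export
compute_features <- function(fit, stack = NULL) {
  F1 <- feature_f1(fit)
  F2 <- feature_f2(fit)
  F3 <- feature_f3(fit, stack)
  n <- length(F1)
  P <- if (n >= 2L) derivative_product(F1, F2, F3) else numeric(0)
  out <- data.frame(frame = seq_len(n), F1 = as.numeric(F1), F2 = F2, F3 = F3,
                    dF1 = c(NA, diff(F1)), dF2 = c(NA, diff(F2)),
                    dF3 = c(NA, diff(F3)), P = c(NA, P))
  class(out) <- c("feature_series", class(out))
  out
}
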