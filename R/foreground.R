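# Gaussian smoothing with a FWHM-matched kernel (replicated borders).
gauss_smooth <- function(frame, sigma) {
  sz <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  sz <- min(sz, 2L * (min(dim(frame)) %/% 2L) - 1L)  # brush must fit the image
  if (sz < 3L) return(frame)
  br <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigma)
  EBImage::imageData(EBImage::filter2(frame, br, boundary = "replicate"))
}

#' Estimate the intensity foreground of a frame
#'
#' Smooths the frame with the nucleus-scale Gaussian kernel (`sigma_nuc`)
#' and thresholds it with Otsu's method.  The mask anchors component
#' centers (through the distance-map penalty), restricts seed detection and
#' supplies random fallback locations during initialization.
#'
#' @param frame image matrix.
#' @param priors a [nucleus_priors()] object.
#' @return logical matrix with attribute `"empty"`: `TRUE` when the frame is
#'   constant (no contrast) and the mask is all-`FALSE`.
#' @export
estimate_foreground <- function(frame, priors) {
  sm <- gauss_smooth(frame, priors$sigma_nuc)
  rg <- range(sm)
  # treat FFT-level ripple on a flat frame as no contrast
  if (diff(rg) < 1e-8 * max(1, abs(rg[2]))) {
    return(structure(matrix(FALSE, nrow(frame), ncol(frame)), empty = TRUE))
  }
  thr <- EBImage::otsu(sm, range = rg, levels = 256L)
  structure(sm > thr, empty = FALSE, smoothed = sm)
}

#' Detect nucleus seed locations
#'
#' Local maxima of the smoothed frame, restricted to the Otsu foreground,
#' with a minimum separation of half a nucleus diameter (closer maxima are
#' suppressed in favour of the brighter one).  Seeds initialize component
#' centers on the first frame and attract them on later frames.
#'
#' @inheritParams estimate_foreground
#' @param foreground optional precomputed [estimate_foreground()] result for
#'   `frame` (avoids re-smoothing).
#' @return data frame with columns `x`, `y` (0-based pixel coordinates) and
#'   `intensity` (smoothed value), ordered by decreasing intensity with ties
#'   broken by row-major position.  Zero rows when nothing is found.
#' @export
detect_seeds <- function(frame, priors, foreground = NULL) {
  fg <- if (is.null(foreground)) estimate_foreground(frame, priors) else foreground
  empty <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
  if (attr(fg, "empty")) return(empty)
  sm <- attr(fg, "smoothed")
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3L || nc < 3L) return(empty)
  # strict 8-neighbourhood local maxima (ties to the first in row-major order)
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  ismax <- matrix(TRUE, nr - 2L, nc - 2L)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & (ctr >= sm[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)])
  }
  ismax <- ismax & fg[2:(nr - 1), 2:(nc - 1)]
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  y <- idx[, 1]; x <- idx[, 2]        # already 0-based wrt the full image
  val <- ctr[idx]
  ord <- order(-val, y, x)
  x <- x[ord]; y <- y[ord]; val <- val[ord]
  # greedy minimum-separation suppression, brightest first
  min_sep <- priors$d_nuc / 2
  keep <- logical(length(x))
  for (i in seq_along(x)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (x[keep] - x[i])^2 + (y[keep] - y[i])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  data.frame(x = x[keep], y = y[keep], intensity = val[keep])
}
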