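#' Correct uneven illumination of a pattern image
#'
#' Contrast-limited adaptive histogram equalization (8 x 8 tile grid)
#' flattens the illumination bias of a full-field pattern image so that
#' every micropattern reaches a comparable intensity; the output is
#' rescaled to `[0, 1]`.  Constant images are returned unchanged.
#'
#' @param pattern_image 2D image matrix.
#' @return corrected matrix with values in `[0, 1]`.
#' @export
correct_illumination <- function(pattern_image) {
  stopifnot(is.matrix(pattern_image))
  rg <- range(pattern_image)
  if (diff(rg) <= .Machine$double.eps * max(1, abs(rg[2]))) return(pattern_image)
  x <- (pattern_image - rg[1]) / diff(rg)
  # clahe needs dimensions divisible by the tile grid: pad by edge
  # replication and crop back afterwards
  nr <- nrow(x); nc <- ncol(x)
  pr <- (8L - nr %% 8L) %% 8L
  pc <- (8L - nc %% 8L) %% 8L
  xp <- x[c(seq_len(nr), rep(nr, pr)), c(seq_len(nc), rep(nc, pc))]
  out <- EBImage::imageData(EBImage::clahe(xp, nx = 8L, ny = 8L, limit = 4))
  out <- out[seq_len(nr), seq_len(nc)]
  rg2 <- range(out)
  if (diff(rg2) > 0) out <- (out - rg2[1]) / diff(rg2)
  out
}

#' Locate micropatterns in a corrected pattern image
#'
#' Smooths the image at half the pattern diameter and takes local maxima
#' with a minimum separation of one pattern diameter; patterns whose crop
#' window would cross the field border are excluded.
#'
#' @param corrected illumination-corrected pattern image matrix.
#' @param pattern_diameter micropattern diameter in pixels.
#' @param window crop half-size in pixels used for the border exclusion
#'   and later cropping (default 1.5 pattern diameters, i.e. a square
#'   window three diameters wide).
#' @param min_intensity smoothed-intensity cutoff (relative to the maximum)
#'   below which maxima are ignored as background ripple.
#' @return an object of class `"pattern_layout"`: data frame of centers
#'   (`x`, `y`, 0-based pixels) with the window and diameter attached as
#'   attributes.
#' @export
locate_patterns <- function(corrected, pattern_diameter,
                            window = round(1.5 * pattern_diameter),
                            min_intensity = 0.5) {
  sm <- gauss_smooth(corrected, pattern_diameter / 2)
  nr <- nrow(sm); nc <- ncol(sm)
  if (diff(range(sm)) < 1e-8 * max(1, max(abs(sm)))) {
    return(structure(data.frame(x = numeric(0), y = numeric(0)),
                     window = window, pattern_diameter = pattern_diameter,
                     class = c("pattern_layout", "data.frame")))
  }
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  ismax <- matrix(TRUE, nr - 2L, nc - 2L)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & (ctr >= sm[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)])
  }
  idx <- which(ismax & ctr >= min_intensity * max(sm), arr.ind = TRUE)
  lay <- data.frame(x = numeric(0), y = numeric(0))
  if (nrow(idx) > 0L) {
    y <- idx[, 1]; x <- idx[, 2]   # 0-based in the full image
    val <- ctr[idx]
    ord <- order(-val, y, x)
    x <- x[ord]; y <- y[ord]
    keep <- logical(length(x))
    for (i in seq_along(x)) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      d2 <- (x[keep] - x[i])^2 + (y[keep] - y[i])^2
      keep[i] <- all(d2 >= pattern_diameter^2)
    }
    x <- x[keep]; y <- y[keep]
    inside <- x >= window & x <= nc - 1 - window &
              y >= window & y <= nr - 1 - window
    lay <- data.frame(x = x[inside], y = y[inside])
    lay <- lay[order(lay$y, lay$x), , drop = FALSE]
    rownames(lay) <- NULL
  }
  structure(lay, window = window, pattern_diameter = pattern_diameter,
            class = c("pattern_layout", class(lay)))
}

#' Crop one sub-video per micropattern
#'
#' Cuts a fixed square window (side `2 * window + 1`) around every layout
#' center from each frame of the full-field stack, producing one
#' single-cluster video per micropattern plus an index table mapping
#' sub-stack ids to field coordinates.
#'
#' @param stack full-field stack (3D array or list of matrices).
#' @param layout a [locate_patterns()] result (or any data frame of `x`,
#'   `y` centers with a `window` attribute).
#' @param window crop half-size; defaults to the layout's.
#' @return list with `stacks` (list of cropped 3D arrays, one per pattern)
#'   and `index` (data frame `id`, `cx`, `cy`).
#' @export
crop_sequences <- function(stack, layout, window = attr(layout, "window")) {
  frames <- as_frame_list(stack)
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  stopifnot(!is.null(window))
  out <- list()
  idx <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0))
  for (j in seq_len(nrow(layout))) {
    cx <- round(layout$x[j]); cy <- round(layout$y[j])
    if (cx - window < 0 || cx + window > nc - 1 ||
        cy - window < 0 || cy + window > nr - 1) next
    sub <- array(0, c(2L * window + 1L, 2L * window + 1L, length(frames)))
    for (t in seq_along(frames))
      sub[, , t] <- frames[[t]][(cy - window):(cy + window) + 1L,
                                (cx - window):(cx + window) + 1L]
    out[[length(out) + 1L]] <- sub
    idx <- rbind(idx, data.frame(id = length(out), cx = cx, cy = cy))
  }
  list(stacks = out, index = idx)
}

#' Pre-screen a cropped sequence before fitting
#'
#' Rough first-frame triage mirroring the manual exclusion of unusable
#' patterns: an empty Otsu foreground means no cells; a foreground area
#' above `area_factor` times the nucleus area prior means too many cells
#' to start from two.  Because the mask is taken on the kernel-smoothed
#' frame, each nucleus contributes roughly 2.5 `A_nuc` of mask area; the
#' default factor of 9 passes clusters of up to about three cells and
#' flags larger ones.
#'
#' @param stack cropped sequence (3D array or list of matrices).
#' @param priors a [nucleus_priors()] object.
#' @param area_factor foreground-area threshold in units of `A_nuc`.
#' @return `NULL` when the sequence passes, otherwise the exclusion reason
#'   (`"no cells"` or `"too many cells at start"`).
#' @export
prescreen_sequence <- function(stack, priors, area_factor = 9) {
  frame <- as_frame_list(stack)[[1]]
  fg <- estimate_foreground(frame, priors)
  if (attr(fg, "empty") || !any(fg)) return("no cells")
  if (sum(fg) > area_factor * priors$A_nuc) return("too many cells at start")
  NULL
}
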