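#' Detect the two-to-three-cell transition in a feature series
#'
#' Scans the derivative product for its first clear peak: candidate frames
#' are local maxima of `P` exceeding `median(P) + c * mad(P)`, with an
#' absolute floor `c_abs` on the threshold.  The product multiplies three
#' derivatives that are each normalized by their robust scale, so `P` is
#' dimensionless: the floor demands that the three normalized derivatives
#' exceed `c_abs^(1/3)` robust scales on geometric average, which keeps
#' chance coincidences of small positive noise increments (against which
#' the median/MAD of a mostly-zero series is powerless) from qualifying.
#' The default floor of 27 (three robust scales per factor) sits about
#' twice above the largest product that chance coincidences reach on
#' simulated division-free sequences, while genuine division peaks run
#' one to two orders of magnitude higher.  The earliest qualifying peak
#' is called: it marks the first frame containing three cells.
#'
#' @param x a `"feature_series"` from [compute_features()], or a numeric
#'   derivative-product series aligned to frames `2..n`.
#' @param c threshold multiplier on the robust spread of `P`.
#' @param c_abs absolute threshold floor in normalized-product units.
#' @return an object of class `"event_call"`: either `event_frame` (and
#'   `peak_value`) or `excluded_reason`, plus the `threshold` used.
#' @export
detect_transition <- function(x, c = 5, c_abs = 27) {
  if (inherits(x, "feature_series")) {
    P <- x$P[-1]
    first_frame <- 2L
  } else {
    P <- as.numeric(x)
    first_frame <- 2L
  }
  if (length(P) < 4L)
    stop("derivative-product series too short for peak detection")
  med <- stats::median(P)
  sc <- stats::mad(P)
  if (!is.finite(sc) || sc == 0) {
    rest <- P[-which.max(P)]
    sc <- stats::sd(rest)
    if (!is.finite(sc)) sc <- 0
  }
  thr <- max(med + c * sc, c_abs)
  idx <- which(P > thr)
  idx <- idx[idx > 1L & idx < length(P)]
  idx <- idx[P[idx] >= P[idx - 1L] & P[idx] >= P[idx + 1L]]
  if (length(idx) == 0L) {
    return(structure(list(event_frame = NULL, peak_value = NULL,
                          threshold = thr,
                          excluded_reason = "no significant peak"),
                     class = "event_call"))
  }
  i <- idx[1L]
  structure(list(event_frame = i + first_frame - 1L, peak_value = P[i],
                 threshold = thr, excluded_reason = NULL),
            class = "event_call")
}

#' Detect the division event of a fitted sequence
#'
#' Convenience wrapper: computes the feature series of a [fit_nuclei()]
#' result and runs [detect_transition()] on its derivative product.
#'
#' @param fit a [fit_nuclei()] result.
#' @param c,c_abs passed to [detect_transition()].
#' @return an `"event_call"` object.
#' @export
detect_division <- function(fit, c = 5, c_abs = 27) {
  detect_transition(compute_features(fit), c = c, c_abs = c_abs)
}

#' @export
print.event_call <- function(x, ...) {
  if (is.null(x$event_frame)) {
    cat(sprintf("No division event called (%s); threshold %.3g\n",
                x$excluded_reason, x$threshold))
  } else {
    cat(sprintf("Division event at frame %d (peak %.3g, threshold %.3g)\n",
                x$event_frame, x$peak_value, x$threshold))
  }
  invisible(x)
}
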