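#' Identify the daughter components of a 3-component fit
#'
#' Freshly divided nuclei are the two smallest Gaussian objects of the
#' 3-component model at the transition frame.  Size is the covariance
#' determinant; determinants that agree within `det_tol` (relative) are
#' treated as tied and ranked by peak intensity instead.  The area penalty
#' holds every determinant close to the common prior, so genuinely
#' distinct determinants are rare and the intensity tie-break does most of
#' the discrimination in practice: a component spread over a still-compact
#' daughter fits best with a reduced peak.
#'
#' @param fit3 a `"frame_fit"` with `K = 3` (or a [mixture_params()] of 3).
#' @param det_tol relative tolerance under which determinants count as tied.
#' @return integer vector of the two daughter component indices.
#' @export
identify_daughters <- function(fit3, det_tol = 0.02) {
  params <- if (inherits(fit3, "frame_fit")) fit3$params else fit3
  comps <- as_component_list(params)
  stopifnot(length(comps) == 3L)
  dets <- vapply(comps, function(cp) det(cp$S), numeric(1))
  ws <- vapply(comps, `[[`, numeric(1), "w")
  scale <- max(abs(dets), .Machine$double.eps)
  # order by determinant, breaking near-ties (relative det_tol) by weight:
  # ranking by the pair (quantized det, w) implements both rules at once
  qdet <- round(dets / (det_tol * scale))
  ord <- order(qdet, ws)
  sort(ord[1:2])
}

#' Division angle at the detected transition frame
#'
#' The division axis is the line through the two daughter centers of the
#' 3-component fit at the event frame; the mother axis is the line through
#' the two centers of the 2-component fit one frame earlier (the last
#' frame on which the two-cell description was valid).  Both axes are
#' undirected, so the angle between them is folded into `[0, 90]` degrees
#' via the absolute cosine.
#'
#' @param fit3_at_event `"frame_fit"` with `K = 3` at the event frame.
#' @param fit2_before `"frame_fit"` with `K = 2` at the frame before.
#' @param event_frame optional integer recorded in the result.
#' @param pattern_center optional `c(x, y)` of the micropattern center; when
#'   given, the distance from the division midpoint to it is recorded.
#' @param det_tol passed to [identify_daughters()].
#' @return an object of class `"angle_result"`: `angle` (degrees in
#'   `[0, 90]`), `daughter_indices`, `mother_axis`, `division_axis` (unit
#'   vectors), `event_frame`, `distance_to_pattern_center`.
#' @export
division_angle <- function(fit3_at_event, fit2_before, event_frame = NULL,
                           pattern_center = NULL, det_tol = 0.02) {
  p3 <- if (inherits(fit3_at_event, "frame_fit")) fit3_at_event$params else fit3_at_event
  p2 <- if (inherits(fit2_before, "frame_fit")) fit2_before$params else fit2_before
  c3 <- as_component_list(p3); c2 <- as_component_list(p2)
  stopifnot(length(c3) == 3L, length(c2) == 2L)
  dg <- identify_daughters(p3, det_tol = det_tol)
  a <- c3[[dg[1]]]$mu; b <- c3[[dg[2]]]$mu
  dvec <- a - b
  if (sqrt(sum(dvec^2)) < .Machine$double.eps^0.5)
    stop("degenerate division axis: coincident daughter centers")
  mvec <- c2[[1]]$mu - c2[[2]]$mu
  if (sqrt(sum(mvec^2)) < .Machine$double.eps^0.5)
    stop("degenerate mother axis: coincident centers in the 2-component fit")
  dvec <- dvec / sqrt(sum(dvec^2))
  mvec <- mvec / sqrt(sum(mvec^2))
  ang <- acos(min(1, abs(sum(dvec * mvec)))) * 180 / pi
  mid <- (a + b) / 2
  dist <- if (is.null(pattern_center)) NA_real_ else
    sqrt(sum((mid - pattern_center)^2))
  structure(list(angle = ang, daughter_indices = dg,
                 mother_axis = mvec, division_axis = dvec,
                 event_frame = event_frame,
                 distance_to_pattern_center = dist),
            class = "angle_result")
}

#' @export
print.angle_result <- function(x, ...) {
  cat(sprintf("Division angle: %.2f deg (daughters %d & %d%s)\n",
              x$angle, x$daughter_indices[1], x$daughter_indices[2],
              if (is.null(x$event_frame)) "" else
                sprintf(", event frame %d", x$event_frame)))
  invisible(x)
}

#' Measure the division angle of a fitted sequence
#'
#' Convenience wrapper combining [detect_division()] (or a supplied event
#' call) with [division_angle()] at the detected frame.
#'
#' @param fit a [fit_nuclei()] result.
#' @param event optional `"event_call"`; detected from `fit` when missing.
#' @param pattern_center optional `c(x, y)` pattern center (defaults to the
#'   frame center, appropriate for centered micropattern crops).
#' @param ... passed to [detect_division()].
#' @return an `"angle_result"`, or the excluding `"event_call"` when no
#'   event was found or the event falls on the first frame.
#' @export
measure_division <- function(fit, event = NULL, pattern_center = NULL, ...) {
  if (is.null(event)) event <- detect_division(fit, ...)
  if (is.null(event$event_frame)) return(event)
  t <- event$event_frame
  if (t < 2L) {
    event$excluded_reason <- "event on first frame: no mother axis"
    event$event_frame <- NULL
    return(event)
  }
  if (is.null(pattern_center)) {
    shp <- dim(fit$stack[[1]])
    pattern_center <- c((shp[2] - 1) / 2, (shp[1] - 1) / 2)
  }
  division_angle(fit$fits3[[t]], fit$fits2[[t - 1L]], event_frame = t,
                 pattern_center = pattern_center)
}
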