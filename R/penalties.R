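#' Distance penalty map
#'
#' The location penalty needs, for every pixel, the Euclidean distance to
#' the nearest foreground pixel: zero on the foreground itself, growing
#' outside it.  Component centers are charged the square of this distance,
#' which keeps them from wandering off the cells.
#'
#' @param foreground logical (or 0/1) matrix marking foreground pixels.
#' @return an object of class `"distance_map"`: the distance matrix with the
#'   generating mask attached as attribute `"foreground"`.
#' @export
build_distance_map <- function(foreground) {
  fg <- foreground != 0
  if (!any(fg)) stop("empty foreground mask: no cells to anchor the model")
  if (all(fg)) {
    D <- matrix(0, nrow(fg), ncol(fg))
  } else {
    # EBImage::distmap on the complement: background pixels get the exact
    # Euclidean distance to the closest foreground pixel.
    D <- EBImage::imageData(EBImage::distmap(1 - fg, metric = "euclidean"))
  }
  structure(D, foreground = fg, class = c("distance_map", class(D)))
}

# Distance map lookup at a (possibly off-image) continuous center.
# The center is rounded to its nearest pixel; centers outside the image are
# charged the value at the clamped border pixel plus the out-of-bounds offset.
sample_distance <- function(D, mu) {
  nr <- nrow(D); nc <- ncol(D)
  xi <- round(mu[1]); yi <- round(mu[2])
  xc <- min(max(xi, 0), nc - 1)
  yc <- min(max(yi, 0), nr - 1)
  D[yc + 1, xc + 1] + sqrt((xi - xc)^2 + (yi - yc)^2)
}

#' Location penalty
#'
#' Sum over components of the squared distance-map value at the component
#' center: zero while all centers sit on the intensity foreground, rising
#' quadratically as any center leaves it.
#'
#' @param params mixture parameters (see [render_mixture()] for accepted forms).
#' @param dmap a [build_distance_map()] result.
#' @return scalar penalty `f_loc`.
#' @export
location_penalty <- function(params, dmap) {
  comps <- as_component_list(params)
  sum(vapply(comps, function(cp) sample_distance(dmap, cp$mu)^2, numeric(1)))
}

#' Area penalty
#'
#' Sum over components of the squared deviation of the covariance
#' determinant from the area prior `A_nuc`, discouraging components from
#' collapsing or ballooning relative to a typical nucleus.
#'
#' @inheritParams location_penalty
#' @param priors a [nucleus_priors()] object.
#' @return scalar penalty `f_vol`.
#' @export
area_penalty <- function(params, priors) {
  comps <- as_component_list(params)
  sum(vapply(comps, function(cp) (det(cp$S) - priors$A_nuc)^2, numeric(1)))
}

#' Intensity penalty
#'
#' Sum over components of the squared deviation of the peak intensity from
#' the intensity prior `w_nuc`; without it a component may fade away and end
#' up modelling the background.
#'
#' @inheritParams area_penalty
#' @return scalar penalty `f_int`.
#' @export
intensity_penalty <- function(params, priors) {
  comps <- as_component_list(params)
  sum(vapply(comps, function(cp) (cp$w - priors$w_nuc)^2, numeric(1)))
}

#' Penalized global fitting error
#'
#' The objective minimized on every frame:
#' `f_global = f_err * (1 + f_loc + f_vol + f_int)`, where `f_err` is the
#' raw least-squares residual and the three penalties are
#' [location_penalty()], [area_penalty()] and [intensity_penalty()].  The
#' multiplicative form leaves any zero-residual optimum untouched while
#' inflating the error sharply outside the plausible parameter range.
#'
#' @param frame observed image matrix.
#' @inheritParams area_penalty
#' @param dmap a [build_distance_map()] result for this frame.
#' @return scalar `f_global`, with the four terms attached as attribute
#'   `"components"` (named `f_err`, `f_loc`, `f_vol`, `f_int`).
#' @export
global_error <- function(frame, params, dmap, priors) {
  f_err <- residual_error(frame, render_mixture(params, dim(frame)))
  f_loc <- location_penalty(params, dmap)
  f_vol <- area_penalty(params, priors)
  f_int <- intensity_penalty(params, priors)
  structure(f_err * (1 + f_loc + f_vol + f_int),
            components = c(f_err = f_err, f_loc = f_loc,
                           f_vol = f_vol, f_int = f_int))
}
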