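#' Gaussian component of a nucleus mixture model
#'
#' One nucleus is modelled as an anisotropic 2D Gaussian intensity blob
#' `w * exp(-0.5 * (x - mu)' S^-1 (x - mu))`, fully described by six scalars:
#' the peak intensity `w`, the center `mu = (x, y)` and the three free
#' entries of the symmetric 2x2 covariance matrix `S`.
#'
#' Coordinates are 0-based and pixel-centered: `mu = c(0, 0)` is the center
#' of the pixel stored at `frame[1, 1]`, with `x` running along columns and
#' `y` along rows.
#'
#' @param w peak intensity (grey levels, > 0).
#' @param mu numeric length-2 center `c(x, y)` in pixels.
#' @param S symmetric 2x2 covariance matrix (pixels^2); alternatively a
#'   numeric length-3 vector `c(sigma1_sq, sigma2_sq, sigma12)`.
#' @return an object of class `"gaussian_component"`.
#' @export
gaussian_component <- function(w, mu, S) {
  if (is.numeric(S) && length(S) == 3L)
    S <- matrix(c(S[1], S[3], S[3], S[2]), 2, 2)
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w),
            is.numeric(mu), length(mu) == 2L, all(is.finite(mu)),
            is.matrix(S), all(dim(S) == c(2L, 2L)), all(is.finite(S)))
  if (abs(S[1, 2] - S[2, 1]) > 1e-9 * (abs(S[1, 2]) + 1e-12))
    stop("covariance matrix is not symmetric")
  S[1, 2] <- S[2, 1] <- (S[1, 2] + S[2, 1]) / 2
  structure(list(w = as.numeric(w), mu = as.numeric(mu), S = S),
            class = "gaussian_component")
}

#' Mixture parameters
#'
#' An ordered set of [gaussian_component()]s: the full parameter vector of a
#' K-component nucleus mixture (12 free scalars for K = 2, 18 for K = 3).
#'
#' @param components list of [gaussian_component()] objects (length 2 or 3).
#' @return an object of class `"mixture_params"`.
#' @export
mixture_params <- function(components) {
  stopifnot(is.list(components), length(components) %in% c(2L, 3L),
            all(vapply(components, inherits, logical(1), "gaussian_component")))
  structure(list(components = components), class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Mixture of %d Gaussian components\n", n_components(x)))
  for (k in seq_along(x$components)) {
    cp <- x$components[[k]]
    cat(sprintf("  [%d] w = %.4g, mu = (%.2f, %.2f), sigma1^2 = %.3g, sigma2^2 = %.3g, sigma12 = %.3g\n",
                k, cp$w, cp$mu[1], cp$mu[2], cp$S[1, 1], cp$S[2, 2], cp$S[1, 2]))
  }
  invisible(x)
}

# Accept a mixture_params, a list of components, or a single component.
as_component_list <- function(params) {
  if (inherits(params, "mixture_params")) return(params$components)
  if (inherits(params, "gaussian_component")) return(list(params))
  stopifnot(is.list(params),
            all(vapply(params, inherits, logical(1), "gaussian_component")))
  params
}

n_components <- function(params) length(as_component_list(params))

# Flatten to the optimizer vector: (w, mux, muy, s11, s22, s12) per component.
pack_params <- function(params) {
  comps <- as_component_list(params)
  unlist(lapply(comps, function(cp)
    c(cp$w, cp$mu, cp$S[1, 1], cp$S[2, 2], cp$S[1, 2])))
}

unpack_params <- function(v, K = length(v) %/% 6L) {
  comps <- lapply(seq_len(K), function(k) {
    p <- v[(6L * (k - 1L) + 1L):(6L * k)]
    gaussian_component(p[1], p[2:3], c(p[4], p[5], p[6]))
  })
  if (K %in% c(2L, 3L)) mixture_params(comps) else comps
}

#' Render a Gaussian mixture as a model image
#'
#' Evaluates `M(x, y) = sum_k w_k exp(-0.5 (x - mu_k)' S_k^-1 (x - mu_k))`
#' at every pixel center of an `shape[1]` x `shape[2]` image.
#'
#' @param params a [mixture_params()], a list of [gaussian_component()]s, or
#'   a single component.
#' @param shape integer length-2 image dimensions `c(n_rows, n_cols)`.
#' @return numeric matrix of dimension `shape`.
#' @examples
#' cp <- gaussian_component(1, c(5, 5), diag(2))
#' m <- render_mixture(list(cp), c(11, 11))
#' m[6, 6]   # peak: 1
#' m[6, 7]   # one pixel along x: exp(-0.5)
#' @export
render_mixture <- function(params, shape) {
  comps <- as_component_list(params)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  xs <- seq_len(shape[2]) - 1
  ys <- seq_len(shape[1]) - 1
  out <- matrix(0, shape[1], shape[2])
  for (k in seq_along(comps)) {
    cp <- comps[[k]]
    dt <- cp$S[1, 1] * cp$S[2, 2] - cp$S[1, 2]^2
    if (!is.finite(dt) || dt <= 0)
      stop(sprintf("component %d has a singular covariance matrix", k))
    a <-  cp$S[2, 2] / dt
    b <-  cp$S[1, 1] / dt
    cc <- -cp$S[1, 2] / dt
    dx <- xs - cp$mu[1]
    dy <- ys - cp$mu[2]
    # quadratic form q(y, x) = a dx^2 + b dy^2 + 2 c dx dy
    q <- outer(dy^2 * b, dx^2 * a, "+") + 2 * cc * outer(dy, dx)
    out <- out + cp$w * exp(-0.5 * q)
  }
  out
}

#' Least-squares residual between a frame and a model image
#'
#' @param frame observed image matrix.
#' @param model model image matrix of identical dimension.
#' @return the sum of squared pixel differences.
#' @export
residual_error <- function(frame, model) {
  if (!identical(dim(frame), dim(model)))
    stop("frame and model have different dimensions")
  sum((frame - model)^2)
}

#' Eigen-decomposition of a 2x2 covariance matrix
#'
#' Returns the major/minor axis lengths (eigenvalues) of the intensity
#' ellipse and the orientation of its major axis.
#'
#' @param S symmetric positive definite 2x2 matrix.
#' @return list with `lambda1 >= lambda2 > 0` and `theta`, the angle of the
#'   major-axis eigenvector measured counter-clockwise from +x, in degrees
#'   within `(-90, 90]`.
#' @export
covariance_eigen <- function(S) {
  stopifnot(is.matrix(S), all(dim(S) == c(2L, 2L)))
  if (abs(S[1, 2] - S[2, 1]) > 1e-9 * (abs(S[1, 2]) + 1e-12))
    stop("covariance matrix is not symmetric")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("covariance matrix is not positive definite")
  v1 <- e$vectors[, 1L]       # major axis (eigen() sorts decreasing)
  theta <- atan2(v1[2], v1[1]) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90)   theta <- theta - 180
  list(lambda1 = e$values[1L], lambda2 = e$values[2L], theta = theta)
}

rotation_matrix <- function(delta_deg) {
  d <- delta_deg * pi / 180
  matrix(c(cos(d), sin(d), -sin(d), cos(d)), 2, 2)
}

#' Rotate a covariance matrix
#'
#' Applies the similarity transform `R(delta) S R(delta)^-1`, turning the
#' intensity ellipse by `delta` while preserving its axis lengths.  Used to
#' extrapolate a rotating nucleus one frame ahead.
#'
#' @param S symmetric 2x2 covariance matrix.
#' @param delta rotation angle in degrees (counter-clockwise).
#' @return the rotated covariance matrix (symmetric).
#' @export
rotate_covariance <- function(S, delta) {
  R <- rotation_matrix(delta)
  out <- R %*% S %*% t(R)   # R^-1 = R' for a rotation
  (out + t(out)) / 2
}
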