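# Sample `n` uniformly random foreground pixel locations (0-based x/y).
random_foreground_locations <- function(mask, n) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no cells: empty foreground")
  pick <- idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE]
  data.frame(x = pick[, 2] - 1, y = pick[, 1] - 1)
}

#' Initialize mixture parameters on the first frame
#'
#' Component centers are set to the brightest detected seeds; if fewer
#' seeds than components are found (overlapping cells), the remaining
#' centers are drawn uniformly from the foreground.  Every peak intensity
#' starts at the prior `w_nuc`; every covariance starts isotropic with
#' determinant equal to the area prior (`sigma1^2 = sigma2^2 =
#' sqrt(A_nuc)`, `sigma12 = 0`), so the starting point is already
#' consistent with the area penalty.  (Starting at the kernel scale
#' `sigma_nuc` instead puts the determinant four times above the prior,
#' and the penalty then crushes whichever covariance axis the optimizer
#' touches first, locking the ellipse into an arbitrary orientation.)
#'
#' Random fallback locations use the R random number generator: seed it (or
#' pass `seed` to the sequence fitter) for reproducible runs.
#'
#' @param frame image matrix.
#' @param K number of components (2 or 3).
#' @param priors a [nucleus_priors()] object.
#' @param sigma_init `"prior"` (default) starts every covariance at the
#'   isotropic area-prior value; `"bootstrap"` instead runs `n_boot`
#'   quick fits from random foreground starting centers and uses the
#'   component-wise medians of the fitted covariance entries (components
#'   matched to the seed centers by position), mirroring an empirical
#'   shape estimate from the frame itself.
#' @param n_boot number of random-restart fits in bootstrap mode.
#' @param control [powell_control()] used by the bootstrap fits.
#' @return a [mixture_params()] object.
#' @export
init_first_frame <- function(frame, K, priors,
                             sigma_init = c("prior", "bootstrap"),
                             n_boot = 10L, control = powell_control()) {
  stopifnot(K %in% c(2L, 3L))
  sigma_init <- match.arg(sigma_init)
  fg <- estimate_foreground(frame, priors)
  if (attr(fg, "empty") || !any(fg)) stop("no cells: empty foreground")
  seeds <- detect_seeds(frame, priors)
  ctr <- seeds[seq_len(min(nrow(seeds), K)), c("x", "y"), drop = FALSE]
  if (nrow(ctr) < K)
    ctr <- rbind(ctr, random_foreground_locations(fg, K - nrow(ctr)))
  S0 <- diag(2) * sqrt(priors$A_nuc)
  Ss <- rep(list(S0), K)
  if (sigma_init == "bootstrap") {
    dmap <- build_distance_map(fg)
    ent <- array(NA_real_, c(n_boot, K, 3L))   # s11, s22, s12 per component
    for (b in seq_len(n_boot)) {
      rc <- random_foreground_locations(fg, K)
      start <- mixture_params(lapply(seq_len(K), function(k)
        gaussian_component(priors$w_nuc, c(rc$x[k], rc$y[k]), S0)))
      ftb <- fit_frame(frame, start, dmap, priors, control)
      # match fitted components to the seed-based centers by position
      used <- integer(0)
      for (k in seq_len(K)) {
        d <- vapply(ftb$params$components, function(cp)
          sum((cp$mu - c(ctr$x[k], ctr$y[k]))^2), numeric(1))
        d[used] <- Inf
        j <- which.min(d)
        used <- c(used, j)
        S <- ftb$params$components[[j]]$S
        ent[b, k, ] <- c(S[1, 1], S[2, 2], S[1, 2])
      }
    }
    med <- apply(ent, c(2L, 3L), stats::median)
    for (k in seq_len(K)) {
      S <- matrix(c(med[k, 1], med[k, 3], med[k, 3], med[k, 2]), 2, 2)
      if (det(S) > 1e-6) Ss[[k]] <- S
    }
  }
  mixture_params(lapply(seq_len(K), function(k)
    gaussian_component(priors$w_nuc, c(ctr$x[k], ctr$y[k]), Ss[[k]])))
}

#' Initialize mixture parameters from the previous frame's fit
#'
#' Between consecutive frames cells move little but may divide, so each
#' center (and intensity) is initialized halfway between its previous
#' fitted value and the closest local maximum detected on the current
#' frame; with no maxima the previous values carry over unchanged.  Shape
#' and orientation are uncoupled: the covariance is the previous one
#' rotated by the angular step of the previous two frames (constant-speed
#' rotation), or carried over unrotated when no angle history exists.
#'
#' Closest-maximum matching is per-component and independent; two
#' components may elect the same maximum and the subsequent fit resolves
#' the collision.
#'
#' @param prev the previous frame's fitted [mixture_params()].
#' @param frame current image matrix.
#' @param priors a [nucleus_priors()] object.
#' @param prev_theta optional numeric vector of per-component major-axis
#'   orientations (degrees) from the frame before `prev`; `NULL` disables
#'   the rotation extrapolation.
#' @param seeds optional precomputed [detect_seeds()] result for `frame`.
#' @return a [mixture_params()] object.
#' @export
init_next_frame <- function(prev, frame, priors, prev_theta = NULL,
                            seeds = NULL) {
  comps <- as_component_list(prev)
  if (is.null(seeds)) seeds <- detect_seeds(frame, priors)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    cp <- comps[[k]]
    mu <- cp$mu; w <- cp$w
    if (nrow(seeds) > 0L) {
      d2 <- (seeds$x - mu[1])^2 + (seeds$y - mu[2])^2
      j <- which.min(d2)
      sx <- seeds$x[j]; sy <- seeds$y[j]
      mu <- c((mu[1] + sx) / 2, (mu[2] + sy) / 2)
      w  <- (w + frame[sy + 1, sx + 1]) / 2
    }
    S <- cp$S
    if (!is.null(prev_theta)) {
      delta <- covariance_eigen(cp$S)$theta - prev_theta[k]
      # fold to the smallest equivalent turn (axis orientation has period 180)
      delta <- ((delta + 90) %% 180) - 90
      S <- rotate_covariance(cp$S, delta)
    }
    out[[k]] <- gaussian_component(w, mu, S)
  }
  mixture_params(out)
}

# Residual-guided split of one K=2 component into a daughter-like pair:
# the component with the larger squared residual inside a nucleus-sized
# disc is replaced by two components offset along its major axis.  Used as
# an alternative K=3 starting point so that a freshly divided (still
# merged) daughter pair can be captured on the frame where it appears.
split_init_from_fit2 <- function(frame, fit2_params, priors) {
  comps <- as_component_list(fit2_params)
  resid <- frame - render_mixture(comps, dim(frame))
  xs <- seq_len(ncol(frame)) - 1
  ys <- seq_len(nrow(frame)) - 1
  score <- vapply(comps, function(cp) {
    disc <- outer((ys - cp$mu[2])^2, (xs - cp$mu[1])^2, "+") < priors$d_nuc^2
    sum(resid[disc]^2)
  }, numeric(1))
  j <- which.max(score)
  out <- list()
  for (k in seq_along(comps)) {
    cp <- comps[[k]]
    if (k == j) {
      eg <- covariance_eigen(cp$S)
      v1 <- c(cos(eg$theta * pi / 180), sin(eg$theta * pi / 180))
      off <- 0.8 * sqrt(eg$lambda1)
      Sd <- rotate_covariance(diag(c(eg$lambda1 / 2, eg$lambda2)), eg$theta)
      out <- c(out, list(
        gaussian_component(cp$w * 0.65, cp$mu + off * v1, Sd),
        gaussian_component(cp$w * 0.65, cp$mu - off * v1, Sd)))
    } else {
      out <- c(out, list(cp))
    }
  }
  mixture_params(out)
}
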