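# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Control parameters for the Powell fit
#'
#' @param ftol relative tolerance on the objective for the direction-set
#'   convergence test.
#' @param maxit maximum number of direction-set sweeps.
#' @param step_w,step_mu,step_s initial line-search step sizes for the
#'   intensity (fraction of `w_nuc`), center (pixels) and covariance-entry
#'   (pixels^2) coordinates.
#' @param line_tol relative tolerance of the one-dimensional Brent searches.
#' @param restart run one more direction-set pass from the best point when
#'   the first pass hits `maxit` without converging.
#' @param trunc_q squared Mahalanobis radius beyond which a component's
#'   intensity is treated as zero during optimization (exact rendering is
#'   always used for the reported errors).
#' @return a list of class `"powell_control"`.
#' @export
powell_control <- function(ftol = 2e-4, maxit = 60L, step_w = 0.1,
                           step_mu = 0.5, step_s = 1.0, line_tol = 0.08,
                           restart = TRUE, trunc_q = 12) {
  structure(list(ftol = ftol, maxit = as.integer(maxit), step_w = step_w,
                 step_mu = step_mu, step_s = step_s, line_tol = line_tol,
                 restart = isTRUE(restart), trunc_q = trunc_q),
            class = "powell_control")
}

param_steps <- function(K, priors, control) {
  rep(c(control$step_w * priors$w_nuc, control$step_mu, control$step_mu,
        control$step_s, control$step_s, control$step_s), K)
}

#' Fit a K-component mixture model to one frame
#'
#' Minimizes the penalized objective [global_error()] from the given
#' starting parameters with Powell's derivative-free direction-set method.
#' Both the penalized optimum `f_global` and the raw residual `f_err` at
#' the optimum are reported (the residual is what the event features
#' compare between the two model orders).
#'
#' @param frame image matrix.
#' @param init starting [mixture_params()].
#' @param dmap [build_distance_map()] result for this frame.
#' @param priors a [nucleus_priors()] object.
#' @param control a [powell_control()] list.
#' @return an object of class `"frame_fit"`: `params` (optimized
#'   [mixture_params()]), `K`, `f_err`, `f_global`, `penalties`, `theta`
#'   (per-component major-axis orientation, degrees), `converged`,
#'   `n_eval`, `frame_index` (`NA` until placed in a sequence).
#' @export
fit_frame <- function(frame, init, dmap, priors, control = powell_control()) {
  K <- n_components(init)
  steps <- param_steps(K, priors, control)
  res <- cpp_fit_powell(frame, pack_params(init), unclass(dmap),
                        priors$A_nuc, priors$w_nuc, control$ftol,
                        control$maxit, steps, control$trunc_q,
                        control$line_tol)
  # polish passes: restarting with a fresh (axis-aligned) direction set
  # escapes the slow conjugate-direction plateaus that trip the relative
  # convergence test in long curved valleys
  if (control$restart) {
    for (pass in 1:2) {
      res2 <- cpp_fit_powell(frame, res$par, unclass(dmap),
                             priors$A_nuc, priors$w_nuc, control$ftol,
                             control$maxit, steps, control$trunc_q,
                             control$line_tol)
      res2$n_eval <- res$n_eval + res2$n_eval
      improved <- (res$f_global - res2$f_global) >
        10 * control$ftol * abs(res$f_global)
      if (res2$f_global <= res$f_global) res <- res2
      if (!improved) break
    }
  }
  params <- unpack_params(res$par, K)
  fg <- global_error(frame, params, dmap, priors)   # exact, untruncated
  pen <- attr(fg, "components")
  structure(list(frame_index = NA_integer_, K = K, params = params,
                 f_err = unname(pen["f_err"]), f_global = as.numeric(fg),
                 penalties = pen[c("f_loc", "f_vol", "f_int")],
                 theta = vapply(params$components,
                                function(cp) covariance_eigen(cp$S)$theta,
                                numeric(1)),
                 converged = isTRUE(res$converged),
                 n_eval = as.integer(res$n_eval)),
            class = "frame_fit")
}

#' @export
print.frame_fit <- function(x, ...) {
  cat(sprintf("%d-component frame fit: f_err = %.4g, f_global = %.4g (%s)\n",
              x$K, x$f_err, x$f_global,
              if (x$converged) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}

#' Fit paired 2- and 3-component mixture models to a whole sequence
#'
#' The central model fit: every frame of a single-cluster video receives
#' an independent 2-component and 3-component penalized Gaussian mixture
#' fit.  Each K-track is chained through time: the first frame starts from
#' detected seeds ([init_first_frame()]), later frames start halfway
#' between the previous optimum and the nearest current local maximum with
#' the covariance rotated at the extrapolated angular speed
#' ([init_next_frame()]).  For the 3-component track a second candidate
#' start, obtained by splitting the same frame's 2-component fit along the
#' major axis of its worst-explained component, competes with the temporal
#' start; the candidate with the lower penalized error wins.  This lets the
#' third component capture a freshly divided, still strongly overlapping
#' daughter pair on the very frame where it appears.
#'
#' @param stack a numeric 3D array (`rows x cols x frames`) or list of
#'   image matrices.
#' @param priors a [nucleus_priors()] object, or `NULL` to build one from
#'   `d_nuc` and `w_nuc`.
#' @param d_nuc,w_nuc nucleus diameter (pixels) and peak intensity priors,
#'   used when `priors` is `NULL`.
#' @param seed optional integer seed controlling the random fallback
#'   locations used when fewer seeds than components are detected; the
#'   caller's RNG state is restored afterwards.
#' @param control a [powell_control()] list.
#' @param split_candidate logical; disable to fit the 3-component track
#'   from the temporal initialization only.
#' @return an object of class `"nuclei_gmm"` with elements `fits2`,
#'   `fits3` (lists of [fit_frame()] results, one per frame), `priors`,
#'   `stack`, `n_frames` and `call`.  Methods: `print`, `summary`, `coef`,
#'   `residuals`, `fitted`, `plot`.
#' @seealso [detect_division()], [measure_division()], [compute_features()]
#' @export
fit_nuclei <- function(stack, priors = NULL, d_nuc = NULL, w_nuc = NULL,
                       seed = NULL, control = powell_control(),
                       split_candidate = TRUE) {
  frames <- as_frame_list(stack)
  n <- length(frames)
  if (n == 0L) stop("empty image stack")
  if (is.null(priors)) {
    if (is.null(d_nuc) || is.null(w_nuc))
      stop("either `priors` or both `d_nuc` and `w_nuc` must be given")
    priors <- nucleus_priors(d_nuc, w_nuc)
  }
  cl <- match.call()
  with_seed(seed, {
    fits2 <- vector("list", n)
    fits3 <- vector("list", n)
    theta_hist <- list(`2` = NULL, `3` = NULL)  # thetas at t-2 per track
    for (t in seq_len(n)) {
      frame <- frames[[t]]
      fg <- estimate_foreground(frame, priors)
      if (attr(fg, "empty") || !any(fg)) {
        if (t == 1L) stop("no cells: empty foreground on the first frame")
        # carry the previous fit through an empty frame, flagged
        fits2[[t]] <- fits2[[t - 1L]]; fits2[[t]]$converged <- FALSE
        fits3[[t]] <- fits3[[t - 1L]]; fits3[[t]]$converged <- FALSE
        fits2[[t]]$frame_index <- t; fits3[[t]]$frame_index <- t
        next
      }
      dmap <- build_distance_map(fg)
      seeds <- detect_seeds(frame, priors, foreground = fg)
      for (K in c(2L, 3L)) {
        key <- as.character(K)
        prev <- if (t > 1L) (if (K == 2L) fits2[[t - 1L]] else fits3[[t - 1L]])
        init <- if (t == 1L) init_first_frame(frame, K, priors)
                else init_next_frame(prev$params, frame, priors,
                                     prev_theta = theta_hist[[key]],
                                     seeds = seeds)
        ft <- fit_frame(frame, init, dmap, priors, control)
        if (K == 3L && split_candidate) {
          # run the competing split start on the first frame, whenever the
          # 2-component residual jumps above its running median (the
          # signature of a new cell the temporal track may have missed),
          # or when the temporal fit failed to converge
          f2_hist <- vapply(fits2[seq_len(t - 1L)], `[[`, numeric(1), "f_err")
          trigger <- t == 1L || !ft$converged ||
            fits2[[t]]$f_err > 1.15 * stats::median(f2_hist)
          if (trigger) {
            init_s <- split_init_from_fit2(frame, fits2[[t]]$params, priors)
            ft_s <- fit_frame(frame, init_s, dmap, priors, control)
            if (ft_s$f_global < ft$f_global) ft <- ft_s
          }
        }
        ft$frame_index <- t
        theta_hist[[key]] <- if (t > 1L) prev$theta
        if (K == 2L) fits2[[t]] <- ft else fits3[[t]] <- ft
      }
    }
    structure(list(fits2 = fits2, fits3 = fits3, priors = priors,
                   stack = frames, n_frames = n, seed = seed, call = cl),
              class = "nuclei_gmm")
  })
}

as_frame_list <- function(stack) {
  if (is.list(stack)) {
    stopifnot(all(vapply(stack, is.matrix, logical(1))))
    return(stack)
  }
  if (is.array(stack) && length(dim(stack)) == 3L)
    return(lapply(seq_len(dim(stack)[3]), function(i) stack[, , i]))
  if (is.matrix(stack)) return(list(stack))
  stop("stack must be a 3D array or a list of matrices")
}

#' @export
print.nuclei_gmm <- function(x, ...) {
  cat(sprintf("Paired 2-/3-component nucleus mixture fits: %d frames of %d x %d px\n",
              x$n_frames, nrow(x$stack[[1]]), ncol(x$stack[[1]])))
  cat(sprintf("  priors: d_nuc = %.3g px, w_nuc = %.3g\n",
              x$priors$d_nuc, x$priors$w_nuc))
  r <- residuals(x)
  cat(sprintf("  median f_err: %.4g (K=2), %.4g (K=3); f3 <= f2 on %d/%d frames\n",
              stats::median(r[, "f2"]), stats::median(r[, "f3"]),
              sum(r[, "f3"] <= r[, "f2"]), x$n_frames))
  nc <- sum(!vapply(x$fits2, `[[`, logical(1), "converged")) +
        sum(!vapply(x$fits3, `[[`, logical(1), "converged"))
  if (nc > 0) cat(sprintf("  %d frame fits flagged as not converged\n", nc))
  invisible(x)
}

#' @export
summary.nuclei_gmm <- function(object, ...) {
  r <- residuals(object)
  out <- list(n_frames = object$n_frames, priors = object$priors,
              f_err = apply(r, 2, stats::quantile,
                            probs = c(0.05, 0.5, 0.95)),
              ordering_fraction = mean(r[, "f3"] <= r[, "f2"]),
              converged = c(
                K2 = mean(vapply(object$fits2, `[[`, logical(1), "converged")),
                K3 = mean(vapply(object$fits3, `[[`, logical(1), "converged"))))
  class(out) <- "summary.nuclei_gmm"
  out
}

#' @export
print.summary.nuclei_gmm <- function(x, ...) {
  cat(sprintf("Sequence fit over %d frames\n", x$n_frames))
  print(x$priors)
  cat("Raw residual quantiles:\n")
  print(x$f_err)
  cat(sprintf("f3 <= f2 on %.1f%% of frames; converged: %.0f%% (K=2), %.0f%% (K=3)\n",
              100 * x$ordering_fraction, 100 * x$converged["K2"],
              100 * x$converged["K3"]))
  invisible(x)
}

#' Extract fitted mixture parameters
#'
#' @param object a [fit_nuclei()] result.
#' @param K which model order to extract (2, 3 or both).
#' @param ... unused.
#' @return a long-format data frame: one row per frame, model order and
#'   component, with columns `frame`, `K`, `component`, `w`, `mu_x`,
#'   `mu_y`, `sigma1_sq`, `sigma2_sq`, `sigma12`, `theta`, `f_err`,
#'   `f_global`, `converged`.
#' @export
coef.nuclei_gmm <- function(object, K = c(2L, 3L), ...) {
  rows <- list()
  for (kk in K) {
    fits <- if (kk == 2L) object$fits2 else object$fits3
    for (ft in fits) {
      for (j in seq_len(ft$K)) {
        cp <- ft$params$components[[j]]
        rows[[length(rows) + 1L]] <- data.frame(
          frame = ft$frame_index, K = ft$K, component = j,
          w = cp$w, mu_x = cp$mu[1], mu_y = cp$mu[2],
          sigma1_sq = cp$S[1, 1], sigma2_sq = cp$S[2, 2], sigma12 = cp$S[1, 2],
          theta = ft$theta[j], f_err = ft$f_err, f_global = ft$f_global,
          converged = ft$converged)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-frame raw residuals of both model orders
#'
#' @param object a [fit_nuclei()] result.
#' @param ... unused.
#' @return numeric matrix with columns `f2` and `f3`.
#' @export
residuals.nuclei_gmm <- function(object, ...) {
  cbind(f2 = vapply(object$fits2, `[[`, numeric(1), "f_err"),
        f3 = vapply(object$fits3, `[[`, numeric(1), "f_err"))
}

#' Model images reconstructed from the fits
#'
#' @param object a [fit_nuclei()] result.
#' @param K model order to render.
#' @param frames frame indices (default all).
#' @param ... unused.
#' @return 3D array of rendered model images.
#' @export
fitted.nuclei_gmm <- function(object, K = 3L, frames = NULL, ...) {
  fits <- if (K == 2L) object$fits2 else object$fits3
  if (is.null(frames)) frames <- seq_len(object$n_frames)
  shape <- dim(object$stack[[1]])
  out <- array(0, c(shape, length(frames)))
  for (i in seq_along(frames))
    out[, , i] <- render_mixture(fits[[frames[i]]]$params, shape)
  out
}

#' Plot the time features of a sequence fit
#'
#' Draws the three transition features and the derivative product, with
#' the detected transition frame (if any) marked.
#'
#' @param x a [fit_nuclei()] result.
#' @param c peak threshold multiplier passed to [detect_transition()].
#' @param ... unused.
#' @export
plot.nuclei_gmm <- function(x, c = 5, ...) {
  fs <- compute_features(x)
  ev <- detect_transition(fs, c = c)
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  tt <- fs$frame
  graphics::plot(tt, fs$F1, type = "l", xlab = "", ylab = "F1 = f3/f2")
  graphics::plot(tt, fs$F2, type = "l", xlab = "", ylab = "F2 (px)")
  graphics::plot(tt, fs$F3, type = "l", xlab = "", ylab = "F3 (var)")
  graphics::plot(tt, fs$P, type = "h", xlab = "frame", ylab = "P")
  if (!is.null(ev$event_frame))
    graphics::abline(v = ev$event_frame, col = 2, lty = 2)
  invisible(x)
}
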