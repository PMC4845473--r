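#' Scenario for a synthetic cluster video
#'
#' Describes a ground-truthed time-lapse of an isolated micropattern
#' cluster: two nuclei that translate by a random walk and rotate at
#' roughly constant angular speed, optionally dividing into three at a
#' known frame, with additive Gaussian noise and optional per-frame
#' defocus.  Defaults emulate a 60 x 60 px crop with 10 px nuclei imaged
#' at a signal-to-noise ratio of about 10 on a normalized `[0, 1]`
#' intensity scale.
#'
#' @param n_frames number of frames.
#' @param frame_shape image dimensions `c(rows, cols)`.
#' @param d_nuc,w_nuc nucleus diameter (px) and peak intensity priors of
#'   the rendered nuclei.
#' @param division_frame 1-based index of the first frame with three
#'   nuclei, or `NULL` for a video without division; must leave at least
#'   two frames on either side.
#' @param division_angle programmed angle (degrees, `[0, 90]`) between the
#'   daughter axis and the mother-cell axis of the previous frame.
#' @param overlap_fraction daughter overlap at birth: their center
#'   distance is `(1 - overlap_fraction) * d_nuc`.
#' @param motion_sigma per-frame random-walk step (px) of each nucleus.
#' @param rotation_speed per-frame rotation (degrees) of each nucleus
#'   (random sign per nucleus).
#' @param defocus_frames optional integer frames on which one nucleus is
#'   defocused (extra isotropic blur of scale `d_nuc/2`, peak reduced 30%).
#' @param noise_sigma additive Gaussian noise scale (grey levels);
#'   intensities are clipped at zero.
#' @param initial_separation center distance of the two starting nuclei (px).
#' @param separation_rate post-division daughter separation speed, as a
#'   fraction of `d_nuc` per frame over the three frames after birth
#'   (anaphase/telophase elongation).
#' @param seed integer seed; the generator is fully reproducible.
#' @return validated list of class `"cluster_scenario"`.
#' @export
cluster_scenario <- function(n_frames = 100L, frame_shape = c(60L, 60L),
                             d_nuc = 10, w_nuc = 0.5,
                             division_frame = NULL, division_angle = 45,
                             overlap_fraction = 0.3, motion_sigma = 0.3,
                             rotation_speed = 2, defocus_frames = NULL,
                             noise_sigma = 0.05,
                             initial_separation = 1.6 * d_nuc,
                             separation_rate = 0.4, seed = 1L) {
  sc <- list(n_frames = as.integer(n_frames), frame_shape = as.integer(frame_shape),
             d_nuc = d_nuc, w_nuc = w_nuc,
             division_frame = if (!is.null(division_frame)) as.integer(division_frame),
             division_angle = division_angle,
             overlap_fraction = overlap_fraction, motion_sigma = motion_sigma,
             rotation_speed = rotation_speed,
             defocus_frames = if (!is.null(defocus_frames)) as.integer(defocus_frames),
             noise_sigma = noise_sigma,
             initial_separation = initial_separation,
             separation_rate = separation_rate, seed = as.integer(seed))
  bad <- character(0)
  if (sc$n_frames < 2L) bad <- c(bad, "n_frames must be >= 2")
  if (length(sc$frame_shape) != 2L || any(sc$frame_shape < 16L))
    bad <- c(bad, "frame_shape must be two dimensions of at least 16 px")
  if (sc$d_nuc <= 0) bad <- c(bad, "d_nuc must be > 0")
  if (sc$w_nuc <= 0) bad <- c(bad, "w_nuc must be > 0")
  if (!is.null(sc$division_frame) &&
      (sc$division_frame < 3L || sc$division_frame > sc$n_frames - 1L))
    bad <- c(bad, "division_frame must leave at least two frames on either side")
  if (sc$overlap_fraction < 0 || sc$overlap_fraction >= 1)
    bad <- c(bad, "overlap_fraction must be in [0, 1)")
  if (sc$division_angle < 0 || sc$division_angle > 90)
    bad <- c(bad, "division_angle must be in [0, 90] degrees")
  if (sc$noise_sigma < 0) bad <- c(bad, "noise_sigma must be >= 0")
  if (sc$motion_sigma < 0) bad <- c(bad, "motion_sigma must be >= 0")
  if (length(bad)) stop("invalid scenario: ", paste(bad, collapse = "; "))
  structure(sc, class = "cluster_scenario")
}

# covariance matrix with axis lengths (eigenvalues) l1 >= l2 at angle theta
cov_from_axes <- function(l1, l2, theta_deg) {
  rotate_covariance(diag(c(l1, l2)), theta_deg)
}

#' Generate a synthetic cluster video with ground truth
#'
#' Renders every frame as the sum of per-nucleus anisotropic 2D Gaussians
#' (axis ratio drawn from `[1, 2]`, determinant equal to the area prior)
#' plus additive Gaussian noise.  Nuclei random-walk and rotate; at the
#' division frame one nucleus (chosen at random) is replaced by two
#' daughters placed symmetrically along the programmed angle relative to
#' the mother-axis direction recorded one frame earlier.  Daughters are
#' born at half the adult area, growing back linearly over ten frames,
#' and drift apart for three frames (anaphase/telophase separation).
#'
#' @param scenario a [cluster_scenario()].
#' @return list with `stack` (array `rows x cols x n_frames`) and `truth`
#'   (class `"ground_truth"`): per-frame true component lists, the true
#'   `division_frame`, `division_angle`, `mother_axis` and the identity of
#'   the mother nucleus.
#' @export
simulate_cluster_video <- function(scenario) {
  stopifnot(inherits(scenario, "cluster_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    pr <- nucleus_priors(sc$d_nuc, sc$w_nuc)
    A <- pr$A_nuc
    shape <- sc$frame_shape
    ctr <- c((shape[2] - 1) / 2, (shape[1] - 1) / 2)
    phi <- stats::runif(1, 0, 180)
    u0 <- c(cos(phi * pi / 180), sin(phi * pi / 180))
    pos <- list(ctr + sc$initial_separation / 2 * u0,
                ctr - sc$initial_separation / 2 * u0)
    ratio <- stats::runif(2, 1, 2)
    th <- stats::runif(2, 0, 180)
    om <- sc$rotation_speed * sample(c(-1, 1), 2, replace = TRUE)
    mother <- sample.int(2L, 1L)
    div_t <- sc$division_frame
    divdir <- NULL; mother_axis <- NULL
    stack <- array(0, c(shape, sc$n_frames))
    params_by_frame <- vector("list", sc$n_frames)
    for (t in seq_len(sc$n_frames)) {
      if (!is.null(div_t) && t == div_t) {
        ax <- pos[[1]] - pos[[2]]
        mother_axis <- ax / sqrt(sum(ax^2))
        a <- sc$division_angle * pi / 180
        divdir <- c(cos(a) * mother_axis[1] - sin(a) * mother_axis[2],
                    sin(a) * mother_axis[1] + cos(a) * mother_axis[2])
        mp <- pos[[mother]]
        d0 <- (1 - sc$overlap_fraction) * sc$d_nuc
        keep <- setdiff(1:2, mother)
        pos <- c(pos[keep], list(mp + d0 / 2 * divdir, mp - d0 / 2 * divdir))
        ratio <- c(ratio[keep], 1.3, 1.3)
        dth <- atan2(divdir[2], divdir[1]) * 180 / pi
        th <- c(th[keep], dth, dth)
        om <- c(om[keep], sc$rotation_speed * sample(c(-1, 1), 2, replace = TRUE))
      }
      n_nuc <- length(pos)
      comps <- vector("list", n_nuc)
      for (i in seq_len(n_nuc)) {
        dt_i <- A
        if (!is.null(div_t) && t >= div_t && i > n_nuc - 2L) {
          age <- t - div_t
          dt_i <- A * (0.5 + 0.5 * min(age, 10) / 10)
        }
        l1 <- sqrt(dt_i * ratio[i]); l2 <- sqrt(dt_i / ratio[i])
        S <- cov_from_axes(l1, l2, th[i])
        w <- sc$w_nuc
        if (!is.null(sc$defocus_frames) && t %in% sc$defocus_frames && i == 1L) {
          S <- S + diag(2) * (sc$d_nuc / 2)^2
          w <- w * 0.7
        }
        comps[[i]] <- gaussian_component(w, pos[[i]], S)
      }
      img <- render_mixture(comps, shape)
      if (sc$noise_sigma > 0)
        img <- img + matrix(stats::rnorm(prod(shape), 0, sc$noise_sigma),
                            shape[1], shape[2])
      stack[, , t] <- pmax(img, 0)
      params_by_frame[[t]] <- comps
      # dynamics for the next frame
      for (i in seq_len(n_nuc))
        pos[[i]] <- pos[[i]] + stats::rnorm(2, 0, sc$motion_sigma)
      th <- th + om
      if (!is.null(div_t) && t >= div_t && t < div_t + 3L) {
        step <- sc$separation_rate * sc$d_nuc / 2 * divdir
        pos[[n_nuc - 1L]] <- pos[[n_nuc - 1L]] + step
        pos[[n_nuc]] <- pos[[n_nuc]] - step
      }
    }
    truth <- structure(list(params = params_by_frame,
                            division_frame = div_t,
                            division_angle = if (!is.null(div_t)) sc$division_angle,
                            mother_axis = mother_axis,
                            mother_index = mother,
                            scenario = sc),
                       class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' Draw a random K-component mixture for recovery experiments
#'
#' Produces well-posed random truth parameters on a given frame shape:
#' centers at least `1.2 * d_nuc` apart and away from the borders, with
#' fully random orientation and axis ratio (drawn from `[1, 2]`), peak
#' intensities within 10% of the intensity prior and covariance
#' determinants within 3% of the area prior.  Position, shape and
#' orientation - the quantities the downstream angle measurement depends
#' on - are unconstrained; size and intensity stay near the priors
#' because the penalized objective is built on the assumption that the
#' priors describe the data (its area and intensity penalties actively
#' pull fits toward them).  Uses the R random number generator.
#'
#' @param K number of components.
#' @param shape image dimensions `c(rows, cols)`.
#' @param priors a [nucleus_priors()] object.
#' @return a [mixture_params()] (or list of components when `K` is not 2
#'   or 3).
#' @export
random_mixture <- function(K, shape, priors) {
  margin <- priors$d_nuc
  if (any(shape - 1 - 2 * margin <= 0))
    stop("frame shape too small for the nucleus diameter")
  for (try in 1:10000) {
    xs <- stats::runif(K, margin, shape[2] - 1 - margin)
    ys <- stats::runif(K, margin, shape[1] - 1 - margin)
    d2 <- outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2
    if (all(d2[upper.tri(d2)] >= (1.2 * priors$d_nuc)^2)) break
    if (try == 10000)
      stop("could not place ", K, " separated nuclei on this frame shape")
  }
  comps <- lapply(seq_len(K), function(k) {
    dt <- priors$A_nuc * stats::runif(1, 0.97, 1.03)
    r <- stats::runif(1, 1, 2)
    S <- cov_from_axes(sqrt(dt * r), sqrt(dt / r), stats::runif(1, 0, 180))
    gaussian_component(priors$w_nuc * stats::runif(1, 0.9, 1.1),
                       c(xs[k], ys[k]), S)
  })
  if (K %in% c(2L, 3L)) mixture_params(comps) else comps
}

#' Generate a synthetic micropattern field with ground truth
#'
#' Builds a honeycomb (hexagonal grid) pattern-reference image of bright
#' soft-edged disks, optionally shaded by a multiplicative linear
#' illumination ramp, plus a full-field fluorescence stack with cluster
#' videos embedded at a random subset of the patterns.  Grid positions are
#' jittered slightly; disks whose crop window would cross the field
#' border are omitted from the truth layout.
#'
#' @param field_shape full-field dimensions `c(rows, cols)`.
#' @param pattern_diameter disk diameter in pixels.
#' @param spacing center-to-center distance of neighbouring disks
#'   (defaults to 2.5 diameters).
#' @param ramp_factor illumination ratio between the brightest and dimmest
#'   field corner (1 = uniform).
#' @param n_frames frames of the embedded cluster videos.
#' @param cluster_fraction fraction of patterns receiving a cluster.
#' @param window crop half-size defining the border-exclusion zone
#'   (defaults to 1.5 pattern diameters, matching [crop_sequences()]).
#' @param seed integer seed.
#' @return list with `pattern_image`, `stack` (field video), `centers`
#'   (data frame of non-border disk centers `x`, `y`, 0-based),
#'   `cluster_centers` (subset holding clusters) and `clusters` (the
#'   embedded [simulate_cluster_video()] outputs, named by pattern row).
#' @export
simulate_pattern_field <- function(field_shape = c(300L, 300L),
                                   pattern_diameter = 24,
                                   spacing = 2.5 * pattern_diameter,
                                   ramp_factor = 2, n_frames = 2L,
                                   cluster_fraction = 0.4,
                                   window = round(1.5 * pattern_diameter),
                                   seed = 1L) {
  with_seed(seed, {
    nr <- field_shape[1]; nc <- field_shape[2]
    dy <- spacing * sqrt(3) / 2
    rows <- seq(spacing / 2, nr - 1 - spacing / 4, by = dy)
    centers <- NULL
    for (i in seq_along(rows)) {
      offx <- if (i %% 2 == 0) spacing / 2 else 0
      xs <- seq(spacing / 2 + offx, nc - 1 - spacing / 4, by = spacing)
      centers <- rbind(centers, cbind(x = xs, y = rows[i]))
    }
    centers <- centers + matrix(stats::runif(length(centers), -1, 1),
                                nrow(centers), 2)
    inside <- centers[, "x"] >= window & centers[, "x"] <= nc - 1 - window &
              centers[, "y"] >= window & centers[, "y"] <= nr - 1 - window
    centers <- centers[inside, , drop = FALSE]
    xs <- seq_len(nc) - 1; ys <- seq_len(nr) - 1
    pattern <- matrix(0, nr, nc)
    r <- pattern_diameter / 2
    for (j in seq_len(nrow(centers))) {
      d <- sqrt(outer((ys - centers[j, "y"])^2, (xs - centers[j, "x"])^2, "+"))
      pattern <- pattern + 0.8 / (1 + exp(2 * (d - r)))  # soft-edged disk
    }
    ramp <- outer(seq(1, 1, length.out = nr),
                  seq(1 / ramp_factor, 1, length.out = nc))
    pattern <- pattern * ramp
    n_cl <- max(0L, round(cluster_fraction * nrow(centers)))
    pick <- sort(sample.int(nrow(centers), n_cl))
    stack <- array(0, c(nr, nc, n_frames))
    clusters <- list()
    for (j in pick) {
      sc <- cluster_scenario(n_frames = n_frames,
                             frame_shape = c(2L * window + 1L, 2L * window + 1L),
                             seed = sample.int(.Machine$integer.max, 1L))
      cl <- simulate_cluster_video(sc)
      yr <- (round(centers[j, "y"]) - window):(round(centers[j, "y"]) + window)
      xr <- (round(centers[j, "x"]) - window):(round(centers[j, "x"]) + window)
      stack[yr + 1, xr + 1, ] <- stack[yr + 1, xr + 1, ] + cl$stack
      clusters[[as.character(j)]] <- cl
    }
    list(pattern_image = pattern, stack = stack,
         centers = data.frame(x = centers[, "x"], y = centers[, "y"]),
         cluster_centers = data.frame(x = centers[pick, "x"],
                                      y = centers[pick, "y"], index = pick),
         clusters = clusters)
  })
}
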