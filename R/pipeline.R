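#' Run the full division-angle pipeline over many sequences
#'
#' For every single-cluster sequence: pre-screen the first frame
#' ([prescreen_sequence()]), fit the paired mixture models
#' ([fit_nuclei()]), detect the two-to-three-cell transition
#' ([detect_division()]) and, when an event is called, measure the
#' division angle ([measure_division()]).  Sequences are processed in
#' isolation: a failure in one is recorded and the batch continues.
#'
#' @param inputs a list of image stacks (3D arrays or lists of matrices),
#'   or a character vector of TIFF paths, or a single directory containing
#'   `.tif`/`.tiff` files.
#' @param d_nuc,w_nuc nucleus priors (see [nucleus_priors()]).
#' @param c,c_abs peak-threshold settings of [detect_transition()].
#' @param seed integer; each sequence is fitted with `seed` offset by the
#'   rank of its name among the sorted input names, making the batch
#'   reproducible and independent of input order.
#' @param control a [powell_control()].
#' @param area_factor pre-screen threshold of [prescreen_sequence()].
#' @param condition optional condition label stored with every row.
#' @return data frame of class `"division_results"`, one row per input
#'   sequence: `sequence`, `condition`, `status` (`"event"`, `"excluded"`
#'   or `"error"`), `event_frame`, `angle_deg`, `peak_value`, `reason`,
#'   daughter centers, mother-axis vector and
#'   `distance_to_pattern_center`.
#' @export
run_pipeline <- function(inputs, d_nuc, w_nuc, c = 5, c_abs = 27,
                         seed = NULL, control = powell_control(),
                         area_factor = 9, condition = NA_character_) {
  priors <- nucleus_priors(d_nuc, w_nuc)
  if (is.character(inputs)) {
    if (length(inputs) == 1L && dir.exists(inputs))
      inputs <- list.files(inputs, pattern = "\\.tiff?$", full.names = TRUE)
    names(inputs) <- basename(inputs)
    paths <- inputs
    inputs <- as.list(paths)
    attr(inputs, "paths") <- TRUE
  }
  if (length(inputs) == 0L) {
    warning("no input sequences")
    return(empty_results())
  }
  ids <- names(inputs)
  if (is.null(ids)) ids <- as.character(seq_along(inputs))
  seed_rank <- match(ids, sort(unique(ids)))   # stable under input order
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    rows[[i]] <- tryCatch({
      stack <- inputs[[i]]
      if (is.character(stack)) stack <- read_stack(stack)
      reason <- prescreen_sequence(stack, priors, area_factor = area_factor)
      if (!is.null(reason)) {
        result_row(ids[i], condition, "excluded", reason = reason)
      } else {
        fit <- fit_nuclei(stack, priors = priors,
                          seed = if (is.null(seed)) NULL else seed + seed_rank[i],
                          control = control)
        ev <- detect_division(fit, c = c, c_abs = c_abs)
        res <- measure_division(fit, event = ev)
        if (inherits(res, "angle_result")) {
          d <- lapply(res$daughter_indices, function(j)
            fit$fits3[[res$event_frame]]$params$components[[j]]$mu)
          result_row(ids[i], condition, "event",
                     event_frame = res$event_frame, angle = res$angle,
                     peak = ev$peak_value, d1 = d[[1]], d2 = d[[2]],
                     mother_axis = res$mother_axis,
                     dist = res$distance_to_pattern_center)
        } else {
          result_row(ids[i], condition, "excluded", reason = res$excluded_reason)
        }
      }
    }, error = function(e) {
      result_row(ids[i], condition, "error", reason = conditionMessage(e))
    })
  }
  out <- do.call(rbind, rows)
  class(out) <- c("division_results", class(out))
  out
}

result_row <- function(id, condition, status, event_frame = NA_integer_,
                       angle = NA_real_, peak = NA_real_, reason = NA_character_,
                       d1 = c(NA_real_, NA_real_), d2 = c(NA_real_, NA_real_),
                       mother_axis = c(NA_real_, NA_real_), dist = NA_real_) {
  data.frame(sequence = id, condition = condition, status = status,
             event_frame = if (is.null(event_frame)) NA_integer_ else event_frame,
             angle_deg = angle,
             peak_value = if (is.null(peak)) NA_real_ else peak,
             reason = reason,
             daughter1_x = d1[1], daughter1_y = d1[2],
             daughter2_x = d2[1], daughter2_y = d2[2],
             mother_axis_x = mother_axis[1], mother_axis_y = mother_axis[2],
             distance_to_pattern_center = dist,
             stringsAsFactors = FALSE)
}

empty_results <- function() {
  out <- result_row("x", NA_character_, "x")[0, ]
  class(out) <- c("division_results", class(out))
  out
}

#' @export
print.division_results <- function(x, ...) {
  cat(sprintf("Division-angle results: %d sequences\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$status)
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
    exc <- x$reason[x$status != "event" & !is.na(x$reason)]
    if (length(exc)) {
      et <- table(exc)
      for (nm in names(et)) cat(sprintf("    %-28s %d\n", nm, et[[nm]]))
    }
    ang <- x$angle_deg[x$status == "event"]
    if (length(ang))
      cat(sprintf("  angles: n = %d, median = %.1f deg, sd = %.1f deg\n",
                  length(ang), stats::median(ang), stats::sd(ang)))
  }
  invisible(x)
}

#' Compare two division-angle distributions
#'
#' Two-sample Kolmogorov-Smirnov test between the angle samples of two
#' conditions, reported with the medians and standard deviations of both
#' samples.
#'
#' @param sample_a,sample_b numeric vectors of angles in degrees (non-empty);
#'   `"division_results"` data frames are accepted and their event angles
#'   used.
#' @return list of class `"angle_comparison"`: `statistic`, `p_value`,
#'   `median_a`, `median_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
compare_angle_distributions <- function(sample_a, sample_b) {
  get_angles <- function(s) {
    if (inherits(s, "division_results")) s <- s$angle_deg[s$status == "event"]
    as.numeric(s[!is.na(s)])
  }
  a <- get_angles(sample_a); b <- get_angles(sample_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both angle samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b))
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 median_a = stats::median(a), median_b = stats::median(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b)),
            class = "angle_comparison")
}

#' @export
print.angle_comparison <- function(x, ...) {
  cat("Two-sample Kolmogorov-Smirnov comparison of angle distributions\n")
  cat(sprintf("  sample A: n = %d, median = %.1f, sd = %.1f\n",
              x$n_a, x$median_a, x$sd_a))
  cat(sprintf("  sample B: n = %d, median = %.1f, sd = %.1f\n",
              x$n_b, x$median_b, x$sd_b))
  cat(sprintf("  KS statistic = %.4f, p-value = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}
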