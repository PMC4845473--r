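#' Read a grayscale image stack from a multi-page TIFF
#'
#' @param path TIFF file path.
#' @return numeric 3D array (`rows x cols x frames`).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
    p
  })
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write a grayscale image stack to a multi-page TIFF
#'
#' Values are clipped to `[0, 1]` (the range storable in normalized TIFF
#' grey levels); nucleus overlaps in synthetic data can exceed 1 slightly.
#'
#' @param stack 3D array or list of matrices.
#' @param path output TIFF path.
#' @param bits sample depth (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  frames <- as_frame_list(stack)
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' Write the per-frame fit table of a sequence
#'
#' One row per frame, model order and component (see [coef.nuclei_gmm()]).
#'
#' @param fit a [fit_nuclei()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fit, path) {
  utils::write.csv(stats::coef(fit), path, row.names = FALSE)
  invisible(path)
}

#' Write the per-frame feature table of a sequence
#'
#' @param features a [compute_features()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
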