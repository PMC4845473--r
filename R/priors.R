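#' Nucleus priors
#'
#' The whole analysis is driven by two user-set priors that are easy to read
#' off any frame: the average apparent nucleus diameter `d_nuc` (in pixels,
#' interpreted as the full width at half maximum of the intensity profile)
#' and the average peak intensity `w_nuc` (in the grey-level units of the
#' image as read, e.g. `[0, 1]` for normalized TIFF data).
#'
#' Two derived quantities are recomputed on access and never stored:
#' \describe{
#'   \item{`sigma_nuc`}{the Gaussian kernel scale matching the FWHM,
#'     `d_nuc / (2 * sqrt(2 * log(2)))` (pixels);}
#'   \item{`A_nuc`}{the nucleus area prior `pi * d_nuc^2 / 4` (pixels^2),
#'     used as the target for the covariance-determinant penalty.}
#' }
#'
#' @param d_nuc average nucleus diameter in pixels (> 0).
#' @param w_nuc average nucleus peak intensity in grey levels (> 0).
#' @return an object of class `"nucleus_priors"`.
#' @examples
#' pr <- nucleus_priors(d_nuc = 10, w_nuc = 0.5)
#' pr$sigma_nuc  # kernel scale
#' pr$A_nuc      # area prior
#' @export
nucleus_priors <- function(d_nuc, w_nuc) {
  stopifnot(is.numeric(d_nuc), length(d_nuc) == 1L, is.finite(d_nuc), d_nuc > 0,
            is.numeric(w_nuc), length(w_nuc) == 1L, is.finite(w_nuc), w_nuc > 0)
  structure(list(d_nuc = as.numeric(d_nuc), w_nuc = as.numeric(w_nuc)),
            class = "nucleus_priors")
}

#' @export
`$.nucleus_priors` <- function(x, name) {
  switch(name,
         sigma_nuc = unclass(x)$d_nuc / (2 * sqrt(2 * log(2))),
         A_nuc     = pi * unclass(x)$d_nuc^2 / 4,
         unclass(x)[[name]])
}

#' @export
`[[.nucleus_priors` <- function(x, name) `$.nucleus_priors`(x, name)

#' @export
print.nucleus_priors <- function(x, ...) {
  cat("Nucleus priors\n")
  cat(sprintf("  d_nuc     : %.4g px (FWHM)\n", x$d_nuc))
  cat(sprintf("  w_nuc     : %.4g grey levels\n", x$w_nuc))
  cat(sprintf("  sigma_nuc : %.4g px   (derived)\n", x$sigma_nuc))
  cat(sprintf("  A_nuc     : %.4g px^2 (derived)\n", x$A_nuc))
  invisible(x)
}
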