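#' Normalize the brightness statistics of a section plane
#'
#' Rescales a plane to a target mean and standard deviation,
#' \code{Img/sd(Img) * sigma - mean(Img/sd(Img) * sigma) + mu}, cancelling
#' the per-plane brightness variance between survey tiles and sections so a
#' single thresholding policy applies across the stack. The map is affine,
#' so pixel rank order is preserved, and it is idempotent. The sample
#' (n - 1) standard deviation convention is used.
#'
#' @param plane Numeric matrix.
#' @param target_mean Desired output mean (mu), intensity units.
#' @param target_sd Desired output standard deviation (sigma), > 0.
#' @return Matrix with mean `target_mean` and sd `target_sd`.
#' @examples
#' p <- normalize_plane(matrix(c(0, 2), 1), target_mean = 10, target_sd = 1)
#' round(p, 5)  # 9.29289 10.70711
#' @export
normalize_plane <- function(plane, target_mean = 100, target_sd = 20) {
  if (!is.matrix(plane) || !is.numeric(plane))
    stop("'plane' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(plane)))
    stop("non-finite pixels in plane", call. = FALSE)
  stopifnot_scalar_num(target_sd, "target_sd", positive = TRUE)
  s <- stats::sd(plane)
  if (!is.finite(s) || s == 0)
    stop("degenerate plane: zero variance, cannot normalize", call. = FALSE)
  z <- plane / s * target_sd
  z - mean(z) + target_mean
}

#' Flatten slowly varying background on a section plane
#'
#' Homogenizes background brightness by subtracting the local brightness
#' tendency, estimated by Gaussian blurring with reflective border padding:
#' \code{plane - blur(plane, background_sigma)}. Slowly varying gradients
#' are removed while punctate/tubular features much smaller than
#' `background_sigma` are nearly untouched. Negative output values are
#' retained; the thresholder shifts its histogram rather than clipping.
#'
#' @param plane Numeric matrix with finite values.
#' @param background_sigma Blur scale in pixels, > 0 (default 50).
#' @return Matrix of the same dimensions; mean approximately 0 for slowly
#'   varying input.
#' @export
flatten_background <- function(plane, background_sigma = 50) {
  if (!is.matrix(plane) || !is.numeric(plane))
    stop("'plane' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(plane)))
    stop("non-finite pixels in plane", call. = FALSE)
  stopifnot_scalar_num(background_sigma, "background_sigma", positive = TRUE)
  plane - gaussian_blur(plane, background_sigma)
}

#' Preprocess one plane: normalize, then flatten background
#'
#' The fixed pipeline order is normalize then flatten.
#'
#' @inheritParams normalize_plane
#' @inheritParams flatten_background
#' @return Preprocessed matrix.
#' @export
preprocess_plane <- function(plane, target_mean = 100, target_sd = 20,
                             background_sigma = 50) {
  flatten_background(
    normalize_plane(plane, target_mean = target_mean, target_sd = target_sd),
    background_sigma = background_sigma)
}
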