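# Background correction and smoothing.
#
# The background estimate is a grayscale morphological opening with a disc
# whose radius must exceed the nuclear radius, a rolling-ball analogue:
# structures smaller than the disc are flattened into the background and
# subtracted away, so a constant image maps to all zeros. Smoothing is a
# separable Gaussian with reflective borders; it is applied to the nucleus
# channel for segmentation only — intensities are always measured on
# background-corrected but unsmoothed pixels so gates are not blurred.

#' Preprocessing parameters
#'
#' @param background_radius_um structuring-element radius (um) for the
#'   opening-based background estimate; must exceed the expected nuclear
#'   radius or nuclei themselves would be flattened into background.
#'   Default 30 um.
#' @param smooth_sigma_um Gaussian smoothing scale in um (0 disables).
#'   Default 1 um.
#' @param correct_background,smooth_for_segmentation logical step toggles.
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(background_radius_um = 30,
                              smooth_sigma_um = 1,
                              correct_background = TRUE,
                              smooth_for_segmentation = TRUE) {
  if (background_radius_um <= 0) {
    ns_stop("background_radius_um must be > 0", "netscan_param_error")
  }
  if (smooth_sigma_um < 0) {
    ns_stop("smooth_sigma_um must be >= 0", "netscan_param_error")
  }
  structure(
    list(
      background_radius_um = background_radius_um,
      smooth_sigma_um = smooth_sigma_um,
      correct_background = correct_background,
      smooth_for_segmentation = smooth_for_segmentation
    ),
    class = "preprocess_params"
  )
}

# reflect-pad a matrix by k rows/cols on every side
#' @noRd
pad_reflect <- function(m, k) {
  if (k <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  k1 <- min(k, nr); k2 <- min(k, nc)
  ri <- c(rev(seq_len(k1)), seq_len(nr), nr + 1 - seq_len(k1))
  ci <- c(rev(seq_len(k2)), seq_len(nc), nc + 1 - seq_len(k2))
  m[ri, ci, drop = FALSE]
}

#' Estimate and subtract the image background
#'
#' The smooth background is the grayscale opening of the image with a disc
#' of radius `background_radius_um`; the corrected image is
#' `pmax(input - background, 0)`. Reflective padding avoids edge
#' artefacts. A constant image maps to the all-zero image.
#'
#' @param img a [channel_image].
#' @param params a [preprocess_params].
#' @return a [channel_image] of identical dimensions.
#' @export
correct_background <- function(img, params = preprocess_params()) {
  r_px <- um_to_px(params$background_radius_um, img$pixel_size_um)
  if (r_px <= 0) {
    ns_stop("background radius must be positive", "netscan_param_error")
  }
  k <- max(1L, as.integer(round(r_px)))
  maxv <- 2^img$bit_depth - 1
  padded <- pad_reflect(img$pixels, k + 1L)
  bg <- EBImage::opening(padded / maxv, disc_brush(k)) * maxv
  bg <- bg[(k + 2):(k + 1 + nrow(img$pixels)),
           (k + 2):(k + 1 + ncol(img$pixels)), drop = FALSE]
  out <- pmax(img$pixels - bg, 0)
  channel_image(out, bit_depth = img$bit_depth,
                channel_role = img$channel_role,
                pixel_size_um = img$pixel_size_um)
}

# separable Gaussian convolution with reflective borders, sigma in px
#' @noRd
gaussian_smooth_px <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, as.integer(ceiling(4 * sigma_px)))
  x <- seq(-half, half)
  kern <- exp(-x^2 / (2 * sigma_px^2))
  kern <- kern / sum(kern)
  p <- pad_reflect(m, half)
  # stats::filter runs each column; do columns, transpose, columns, transpose
  f1 <- stats::filter(p, kern, sides = 2)
  f2 <- t(stats::filter(t(f1), kern, sides = 2))
  out <- f2[(half + 1):(half + nrow(m)), (half + 1):(half + ncol(m)),
            drop = FALSE]
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Gaussian smoothing
#'
#' @param img a [channel_image].
#' @param params a [preprocess_params]; `smooth_sigma_um = 0` returns the
#'   input unchanged.
#' @return a [channel_image] of identical dimensions.
#' @export
smooth <- function(img, params = preprocess_params()) {
  if (params$smooth_sigma_um < 0) {
    ns_stop("smooth_sigma_um must be >= 0", "netscan_param_error")
  }
  if (params$smooth_sigma_um == 0) return(img)
  sigma_px <- um_to_px(params$smooth_sigma_um, img$pixel_size_um)
  out <- gaussian_smooth_px(img$pixels, sigma_px)
  maxv <- 2^img$bit_depth - 1
  channel_image(pmin(pmax(out, 0), maxv), bit_depth = img$bit_depth,
                channel_role = img$channel_role,
                pixel_size_um = img$pixel_size_um)
}
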