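# The Normalized Fluorescence pipeline: estimate and subtract the additive
# background on both channels, then divide the corrected transfer image by
# the corrected saturation image pixel by pixel. The ratio image carries a
# validity mask excluding pixels whose denominator is too small to divide.

#' Robust background estimate from the inter-pad region
#'
#' Background level and spread are taken as the median and the
#' MAD-derived sigma (1.4826 * MAD) of all pixels outside the pad
#' rectangles, so pad signal never contaminates the estimate and isolated
#' bright pixels have no leverage.
#'
#' @param image Matrix of counts.
#' @param layout A [pad_layout()] locating the pads on the image.
#' @return List with `mean` and `sd`, both in counts.
#' @export
estimate_background <- function(image, layout) {
  stopifnot(is.matrix(image), inherits(layout, "pad_layout"),
            all(dim(image) == layout$image_shape))
  msk <- background_mask(layout)
  if (!any(msk))
    stop("no background region: the pad layout covers the whole image")
  px <- image[msk]
  list(mean = stats::median(px), sd = stats::mad(px))
}

#' Subtract a scalar background, clipping at zero
#'
#' @param image Matrix of counts.
#' @param background List with element `mean` (counts, >= 0), as returned
#'   by [estimate_background()].
#' @return Corrected matrix; negative results are clipped to 0.
#' @export
subtract_background <- function(image, background) {
  stopifnot(is.matrix(image), is.list(background),
            is.numeric(background$mean), background$mean >= 0)
  pmax(image - background$mean, 0)
}

#' Pixel-by-pixel Normalized Fluorescence image
#'
#' Divides the background-corrected transfer image by the
#' background-corrected saturation image wherever the denominator is at
#' least `min_denominator`; all other pixels are marked invalid and carry
#' no value. NF values above 1 (possible on noisy pixels) are retained
#' unclipped so downstream Gaussian fits stay unbiased.
#'
#' @param transfer_corrected,saturation_corrected Background-subtracted
#'   matrices of equal shape.
#' @param min_denominator Positive denominator threshold in counts; a
#'   sensible default is several background sigmas (see
#'   [quantify_image_set()]).
#' @return An object of class `nf_image`: list with `values` (matrix, NA
#'   where invalid), `valid_mask` (logical matrix) and `provenance`.
#' @export
compute_nf_image <- function(transfer_corrected, saturation_corrected,
                             min_denominator) {
  if (!is.matrix(transfer_corrected) || !is.matrix(saturation_corrected) ||
      !all(dim(transfer_corrected) == dim(saturation_corrected)))
    stop("invalid input: transfer and saturation images must be matrices ",
         "of equal shape")
  if (!is.numeric(min_denominator) || length(min_denominator) != 1L ||
      min_denominator <= 0)
    stop("invalid input: min_denominator must be a single positive number")
  valid <- saturation_corrected >= min_denominator
  values <- matrix(NA_real_, nrow(transfer_corrected),
                   ncol(transfer_corrected))
  values[valid] <- transfer_corrected[valid] / saturation_corrected[valid]
  structure(list(values = values, valid_mask = valid,
                 provenance = list(min_denominator = min_denominator)),
            class = "nf_image")
}

#' @export
print.nf_image <- function(x, ...) {
  cat(sprintf("NF image %dx%d px, %d valid pixels (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Display an NF image
#'
#' @param x An `nf_image`.
#' @param zlim Value range for the colour scale.
#' @param ... Passed to [graphics::image()].
#' @export
plot.nf_image <- function(x, zlim = c(0, 1), ...) {
  v <- pmin(pmax(x$values, zlim[1]), zlim[2])
  graphics::image(t(v[nrow(v):1, ]), zlim = zlim, useRaster = TRUE,
                  axes = FALSE, asp = nrow(v) / ncol(v), ...)
  invisible(x)
}
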