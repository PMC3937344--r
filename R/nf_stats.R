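# Per-pad NF read-out: the histogram of valid NF pixels on a pad is
# fitted by a Gaussian, whose mean and standard deviation are the pad's
# reported NF +/- SD. Pads whose transfer signal does not rise above the
# background are assigned NF = 0 without fitting (the zero rule for
# non-binding sequences).

nf_estimate <- function(pad_id = NA, motif_label = NA_character_,
                        reference_n_bp = NA_integer_, nf_mean = NA_real_,
                        nf_sd = NA_real_, n_pixels = 0L,
                        status = c("fitted", "zeroed", "failed"),
                        histogram = NULL) {
  status <- match.arg(status)
  structure(list(pad_id = pad_id, motif_label = motif_label,
                 reference_n_bp = reference_n_bp, nf_mean = nf_mean,
                 nf_sd = nf_sd, n_pixels = as.integer(n_pixels),
                 status = status, histogram = histogram),
            class = "nf_estimate")
}

#' @export
print.nf_estimate <- function(x, ...) {
  if (x$status == "fitted")
    cat(sprintf("NF estimate [%s]: %.3f +/- %.3f (%d px, fitted)\n",
                x$pad_id, x$nf_mean, x$nf_sd, x$n_pixels))
  else
    cat(sprintf("NF estimate [%s]: status %s\n", x$pad_id, x$status))
  invisible(x)
}

#' Gaussian fit to a pad's NF histogram
#'
#' Bins the valid NF pixels of one pad into `bins` uniform bins spanning
#' their range and fits a three-parameter Gaussian (amplitude, mean, sd)
#' to the bin counts by nonlinear least squares, initialised from sample
#' moments. The fitted mean and sd are the pad's NF read-out. With fewer
#' than `min_pixels` valid pixels, or when the fit does not converge, the
#' pad is reported as `failed` (no exception). A degenerate pad whose
#' pixels are all identical is reported at that value with an sd limited
#' by the bin width.
#'
#' @param nf_image An [compute_nf_image()] result.
#' @param pad_mask Logical matrix selecting the pad's pixels.
#' @param bins Number of histogram bins.
#' @param min_pixels Minimum number of valid pixels required to fit.
#' @param pad_id,motif_label,reference_n_bp Optional pad annotation copied
#'   into the estimate.
#' @return An object of class `nf_estimate` with fields `nf_mean`,
#'   `nf_sd`, `n_pixels`, `status` and the histogram used.
#' @export
fit_nf_histogram <- function(nf_image, pad_mask, bins = 100,
                             min_pixels = 500, pad_id = NA,
                             motif_label = NA_character_,
                             reference_n_bp = NA_integer_) {
  stopifnot(inherits(nf_image, "nf_image"), is.logical(pad_mask),
            all(dim(pad_mask) == dim(nf_image$values)))
  vals <- nf_image$values[pad_mask & nf_image$valid_mask]
  n <- length(vals)
  if (n < min_pixels)
    return(nf_estimate(pad_id, motif_label, reference_n_bp,
                       n_pixels = n, status = "failed"))
  rng <- range(vals)
  if (diff(rng) == 0) {
    # delta histogram: mean is exact, spread limited by bin resolution
    w <- if (rng[1] != 0) abs(rng[1]) / bins else 1 / bins
    return(nf_estimate(pad_id, motif_label, reference_n_bp,
                       nf_mean = rng[1], nf_sd = w, n_pixels = n,
                       status = "fitted",
                       histogram = list(bin_edges = rng[1] + c(-w, w) / 2,
                                        counts = n)))
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(vals, breaks = edges, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  start <- list(A = max(counts), mu = mean(vals), s = stats::sd(vals))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A * exp(-(centers - mu)^2 / (2 * s^2)),
      start = start,
      lower = c(A = 0, mu = -Inf, s = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(nf_estimate(pad_id, motif_label, reference_n_bp, n_pixels = n,
                       status = "failed",
                       histogram = list(bin_edges = edges, counts = counts)))
  cf <- stats::coef(fit)
  nf_estimate(pad_id, motif_label, reference_n_bp,
              nf_mean = unname(cf["mu"]), nf_sd = abs(unname(cf["s"])),
              n_pixels = n, status = "fitted",
              histogram = list(bin_edges = edges, counts = counts))
}

#' Zero rule for non-binding pads
#'
#' A pad whose transfer signal sits at the background carries too few
#' transferred fluorophores for a meaningful ratio, so its NF is set to
#' zero instead of being fitted. The decision compares the pad's median
#' raw transfer signal with `background mean + k_sigma * background sd`;
#' the boundary is inclusive (a median exactly at the threshold zeroes
#' the pad).
#'
#' @param transfer_image Raw (uncorrected) transfer image, counts.
#' @param background Background estimate for the transfer channel
#'   (list with `mean`, `sd`).
#' @param pad_mask Logical matrix selecting the pad's pixels.
#' @param k_sigma Exceedance threshold in background sigmas.
#' @return List with `status` (`"zeroed"` or `"fit"`), the pad `median`
#'   and the `threshold` used.
#' @export
apply_zero_rule <- function(transfer_image, background, pad_mask,
                            k_sigma = 3) {
  stopifnot(is.matrix(transfer_image), is.logical(pad_mask),
            all(dim(pad_mask) == dim(transfer_image)))
  med <- stats::median(transfer_image[pad_mask])
  thr <- background$mean + k_sigma * background$sd
  list(status = if (!is.na(med) && med <= thr) "zeroed" else "fit",
       median = med, threshold = thr)
}

#' Are two NF estimates equal within errors?
#'
#' Two fitted pads are considered to report the same NF when the absolute
#' difference of their means does not exceed the sum of their standard
#' deviations — the most permissive reading of "equal within errors"
#' consistent with comparing 0.39 +/- 0.15 to 0.32 +/- 0.01.
#'
#' @param a,b `nf_estimate` objects with `status == "fitted"`.
#' @return TRUE or FALSE.
#' @export
equal_within_errors <- function(a, b) {
  stopifnot(inherits(a, "nf_estimate"), inherits(b, "nf_estimate"))
  if (a$status != "fitted" || b$status != "fitted")
    stop("comparison undefined: both estimates must have status 'fitted' ",
         "(got '", a$status, "' and '", b$status, "')")
  abs(a$nf_mean - b$nf_mean) <= a$nf_sd + b$nf_sd
}

#' Quantify a whole image set
#'
#' Runs the full per-field-of-view pipeline: estimates the background of
#' each channel from the inter-pad region, subtracts it, forms the NF
#' ratio image, then for every pad applies the zero rule on the raw
#' transfer signal and — where it passes — fits the pad's NF histogram.
#'
#' @param image_set An `image_set` (see [render_image_set()] /
#'   [read_image_set()]).
#' @param layout Optional [pad_layout()]; defaults to the one in the image
#'   set's metadata.
#' @param margin_px Pad-mask erosion margin, pixels.
#' @param bins Histogram bins per pad.
#' @param min_pixels Minimum valid pixels per pad for fitting.
#' @param k_sigma Zero-rule threshold in background sigmas.
#' @param min_denominator Denominator threshold for the NF ratio; default
#'   `max(5 * saturation background sd, 1e-6)` counts.
#' @return An object of class `nf_quantification`: list with `pads` (data
#'   frame: pad_id, row, col, motif_label, reference_n_bp, nf_mean, nf_sd,
#'   n_pixels, status), `estimates` (list of `nf_estimate`), `nf_image`,
#'   and `backgrounds`.
#' @export
quantify_image_set <- function(image_set, layout = NULL, margin_px = 2,
                               bins = 100, min_pixels = 500, k_sigma = 3,
                               min_denominator = NULL) {
  stopifnot(inherits(image_set, "image_set"))
  if (is.null(layout)) layout <- image_set$metadata$layout
  stopifnot(inherits(layout, "pad_layout"))
  bg_tr <- estimate_background(image_set$transfer_image, layout)
  bg_sat <- estimate_background(image_set$saturation_image, layout)
  tr_c <- subtract_background(image_set$transfer_image, bg_tr)
  sat_c <- subtract_background(image_set$saturation_image, bg_sat)
  if (is.null(min_denominator))
    min_denominator <- max(5 * bg_sat$sd, 1e-6)
  nf <- compute_nf_image(tr_c, sat_c, min_denominator)
  nf$provenance$background_transfer <- bg_tr
  nf$provenance$background_saturation <- bg_sat
  masks <- segment_pads(layout, margin_px)
  rects <- pad_rects(layout)
  estimates <- vector("list", nrow(rects))
  for (i in seq_len(nrow(rects))) {
    msk <- masks[[rects$pad_id[i]]]
    if (!any(msk)) {
      estimates[[i]] <- nf_estimate(rects$pad_id[i], rects$motif_label[i],
                                    rects$reference_n_bp[i],
                                    status = "failed")
      next
    }
    zr <- apply_zero_rule(image_set$transfer_image, bg_tr, msk, k_sigma)
    if (zr$status == "zeroed") {
      estimates[[i]] <- nf_estimate(rects$pad_id[i], rects$motif_label[i],
                                    rects$reference_n_bp[i], nf_mean = 0,
                                    n_pixels = sum(msk & nf$valid_mask),
                                    status = "zeroed")
    } else {
      estimates[[i]] <- fit_nf_histogram(nf, msk, bins, min_pixels,
                                         pad_id = rects$pad_id[i],
                                         motif_label = rects$motif_label[i],
                                         reference_n_bp =
                                           rects$reference_n_bp[i])
    }
  }
  pads <- data.frame(
    pad_id = rects$pad_id, row = rects$row, col = rects$col,
    motif_label = rects$motif_label, reference_n_bp = rects$reference_n_bp,
    nf_mean = vapply(estimates, function(e) e$nf_mean, numeric(1)),
    nf_sd = vapply(estimates, function(e) e$nf_sd, numeric(1)),
    n_pixels = vapply(estimates, function(e) e$n_pixels, integer(1)),
    status = vapply(estimates, function(e) e$status, character(1)),
    stringsAsFactors = FALSE)
  structure(list(pads = pads, estimates = estimates, nf_image = nf,
                 backgrounds = list(transfer = bg_tr, saturation = bg_sat)),
            class = "nf_quantification")
}

#' @export
print.nf_quantification <- function(x, ...) {
  cat("Per-pad NF quantification:\n")
  print(x$pads[, c("pad_id", "motif_label", "reference_n_bp", "nf_mean",
                   "nf_sd", "status")], row.names = FALSE)
  invisible(x)
}
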