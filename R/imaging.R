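# Synthetic fluorescence read-out: renders seeded transfer/saturation
# image pairs with known per-pad ground truth so the whole NF pipeline can
# be validated without experimental data.

#' Ground truth for a synthetic image pair
#'
#' Collects the physical scene behind one field of view: per-pad protein
#' density (expressed directly in fluorescence counts at saturation),
#' per-pad transfer probability (fraction of constructs whose reference
#' bond ruptured), additive background, and channel noise. Default scales
#' follow the instrument's: background 1500 counts (within the typical
#' 1000-2000 range) and a density of 15500 counts, so a fully transferring
#' pad reads 17000 counts.
#'
#' @param layout A [pad_layout()].
#' @param protein_density Mean saturation signal per pad in counts; scalar
#'   or one value per pad (row-major).
#' @param transfer_probability Per-pad transfer probability in \[0, 1\];
#'   scalar or one value per pad (row-major).
#' @param background_mean,background_sd Additive background level and
#'   per-pixel Gaussian spread, counts.
#' @param multiplicative_noise_cv Coefficient of variation of per-pixel
#'   multiplicative signal noise (Gaussian approximation to photon noise;
#'   counts >> 1).
#' @param read_noise_sd Additive Gaussian read noise, counts.
#' @param inhom_amplitude,inhom_correlation_px Amplitude in \[0, 1) and
#'   correlation length of the smooth protein-density inhomogeneity field
#'   shared between the two channels (the same immobilised molecules are
#'   imaged twice).
#' @param seed Integer seed for rendering.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(layout,
                         protein_density = 15500,
                         transfer_probability = 0.5,
                         background_mean = 1500,
                         background_sd = 100,
                         multiplicative_noise_cv = 0.1,
                         read_noise_sd = 100,
                         inhom_amplitude = 0.2,
                         inhom_correlation_px = 20,
                         seed = 1L) {
  stopifnot(inherits(layout, "pad_layout"))
  n_pads <- layout$grid_rows * layout$grid_cols
  protein_density <- rep(as.numeric(protein_density), length.out = n_pads)
  transfer_probability <- rep(as.numeric(transfer_probability),
                              length.out = n_pads)
  if (any(transfer_probability < 0 | transfer_probability > 1))
    stop("invalid input: transfer_probability must lie in [0, 1]")
  if (background_mean < 0 || background_sd < 0 ||
      multiplicative_noise_cv < 0 || read_noise_sd < 0)
    stop("invalid input: noise parameters must be non-negative")
  if (inhom_amplitude < 0 || inhom_amplitude >= 1)
    stop("invalid input: inhom_amplitude must lie in [0, 1)")
  structure(list(layout = layout,
                 protein_density = protein_density,
                 transfer_probability = transfer_probability,
                 background_mean = as.numeric(background_mean),
                 background_sd = as.numeric(background_sd),
                 multiplicative_noise_cv = as.numeric(multiplicative_noise_cv),
                 read_noise_sd = as.numeric(read_noise_sd),
                 inhom_amplitude = as.numeric(inhom_amplitude),
                 inhom_correlation_px = as.numeric(inhom_correlation_px),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Ground-truth transfer probabilities from the rupture model
#'
#' Maps each pad's (motif, reference length) condition to its transfer
#' probability: the probability that the pad's reference duplex ruptures
#' before the protein-DNA bond, computed by
#' [reference_rupture_probability()]. Motifs absent from `sample_bonds`
#' (e.g. a no-binding sequence, whose protein-DNA complex never forms) get
#' probability 0.
#'
#' @param layout A [pad_layout()].
#' @param sample_bonds Named list of [bell_bond()] objects, one per binding
#'   motif label.
#' @param per_bp_params Per-bp rule for the reference duplexes.
#' @param ramp A [ramp_protocol()].
#' @return Numeric vector, one probability per pad (row-major).
#' @export
transfer_probabilities <- function(layout, sample_bonds,
                                   per_bp_params = default_per_bp_params(),
                                   ramp = ramp_protocol()) {
  rects <- pad_rects(layout)
  vapply(seq_len(nrow(rects)), function(i) {
    motif <- rects$motif_label[i]
    if (!motif %in% names(sample_bonds)) return(0)
    ref <- bond_from_duplex(duplex_spec(rects$reference_n_bp[i]),
                            per_bp_params)
    reference_rupture_probability(sample_bonds[[motif]], ref, ramp)
  }, numeric(1))
}

# Separable circular Gaussian smoothing of a matrix.
smooth2d_gaussian <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sm <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  t(apply(sm, 1, function(row) stats::filter(row, k, circular = TRUE)))
}

#' Smooth multiplicative inhomogeneity field
#'
#' A positive, smooth random field of mean exactly 1 that modulates the
#' protein density identically in both channels: because the NF is a
#' pixel-by-pixel ratio, such shared inhomogeneities cancel exactly.
#' Built from white noise smoothed by a Gaussian kernel of the given
#' correlation length, centred, and scaled so the maximum deviation from 1
#' equals `amplitude`.
#'
#' @param image_shape `(height, width)` in pixels.
#' @param amplitude Maximum relative deviation from 1, in \[0, 1).
#' @param correlation_length_px Smoothing length in pixels, >= 1.
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @return Matrix with `mean == 1` and all values in
#'   `(1 - amplitude, 1 + amplitude)`.
#' @export
make_inhomogeneity_field <- function(image_shape, amplitude,
                                     correlation_length_px, seed = NULL) {
  if (amplitude < 0 || amplitude >= 1)
    stop("invalid input: amplitude must lie in [0, 1)")
  if (correlation_length_px < 1)
    stop("invalid input: correlation_length_px must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (amplitude == 0)
    return(matrix(1, image_shape[1], image_shape[2]))
  z <- matrix(stats::rnorm(prod(image_shape)), image_shape[1], image_shape[2])
  z <- smooth2d_gaussian(z, correlation_length_px)
  z <- z - mean(z)
  mx <- max(abs(z))
  if (mx == 0) return(matrix(1, image_shape[1], image_shape[2]))
  1 + amplitude * z / mx
}

#' Render a synthetic transfer/saturation image pair
#'
#' Renders both fluorescence channels of one field of view. The saturation
#' image shows every functional protein labelled; the transfer image shows
#' only the fraction whose reference bond ruptured:
#' \preformatted{
#'   saturation = bg + D * field * (1 + cv * e1) + read noise
#'   transfer   = bg + D * field * p * (1 + cv * e2) + read noise
#' }
#' where `D` is the pad's protein density, `field` the inhomogeneity field
#' shared between the two channels (the same immobilised proteins are
#' imaged twice), `p` the pad's transfer probability, and all noise terms
#' (background spread, multiplicative `e1`/`e2`, read noise) are drawn
#' independently per pixel and per channel. Counts are clipped to the
#' 16-bit range but kept as doubles in memory.
#'
#' @param layout A [pad_layout()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed (default: the one stored in `truth`).
#' @return An object of class `image_set`: list with `transfer_image`,
#'   `saturation_image` (matrices, counts) and `metadata`.
#' @export
render_image_set <- function(layout, truth, seed = truth$seed) {
  stopifnot(inherits(layout, "pad_layout"), inherits(truth, "ground_truth"))
  shape <- layout$image_shape
  npx <- prod(shape)
  set.seed(as.integer(seed))
  field <- make_inhomogeneity_field(shape, truth$inhom_amplitude,
                                    truth$inhom_correlation_px, seed = NULL)
  density_img <- matrix(0, shape[1], shape[2])
  p_img <- matrix(0, shape[1], shape[2])
  rects <- pad_rects(layout)
  for (i in seq_len(nrow(rects))) {
    rows <- (rects$r0[i] + 1L):rects$r1[i]
    cols <- (rects$c0[i] + 1L):rects$c1[i]
    density_img[rows, cols] <- truth$protein_density[i]
    p_img[rows, cols] <- truth$transfer_probability[i]
  }
  signal_sat <- density_img * field
  render_channel <- function(signal) {
    bg <- truth$background_mean +
      truth$background_sd * matrix(stats::rnorm(npx), shape[1], shape[2])
    mult <- 1 + truth$multiplicative_noise_cv *
      matrix(stats::rnorm(npx), shape[1], shape[2])
    rd <- truth$read_noise_sd * matrix(stats::rnorm(npx), shape[1], shape[2])
    pmin(pmax(bg + signal * mult + rd, 0), 65535)
  }
  saturation <- render_channel(signal_sat)
  transfer <- render_channel(signal_sat * p_img)
  structure(list(
    transfer_image = transfer,
    saturation_image = saturation,
    metadata = list(seed = as.integer(seed), layout = layout,
                    truth = truth, channel = "Cy5")
  ), class = "image_set")
}

#' Write an image set to disk
#'
#' Writes `transfer.tif` and `saturation.tif` as 16-bit grayscale TIFFs
#' (counts rounded to integers) plus `sidecar.json` holding the seed, the
#' layout, and the full ground truth including per-pad transfer
#' probabilities.
#'
#' @param image_set An [render_image_set()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_image_set <- function(image_set, dir) {
  stopifnot(inherits(image_set, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(transfer = file.path(dir, "transfer.tif"),
             saturation = file.path(dir, "saturation.tif"),
             sidecar = file.path(dir, "sidecar.json"))
  tiff::writeTIFF(round(image_set$transfer_image) / 65535,
                  paths[["transfer"]], bits.per.sample = 16L)
  tiff::writeTIFF(round(image_set$saturation_image) / 65535,
                  paths[["saturation"]], bits.per.sample = 16L)
  md <- image_set$metadata
  lay <- md$layout
  truth <- md$truth
  sidecar <- list(
    seed = md$seed, channel = md$channel,
    layout = list(grid_rows = lay$grid_rows, grid_cols = lay$grid_cols,
                  pad_size_px = lay$pad_size_px, pitch_px = lay$pitch_px,
                  image_shape = lay$image_shape, offset_px = lay$offset_px,
                  pad_conditions = lay$pad_conditions),
    truth = list(
      protein_density = truth$protein_density,
      transfer_probability = truth$transfer_probability,
      background_mean = truth$background_mean,
      background_sd = truth$background_sd,
      multiplicative_noise_cv = truth$multiplicative_noise_cv,
      read_noise_sd = truth$read_noise_sd,
      inhom_amplitude = truth$inhom_amplitude,
      inhom_correlation_px = truth$inhom_correlation_px,
      no_binding_pads = pad_rects(lay)$pad_id[
        truth$transfer_probability == 0]
    )
  )
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read an image set written by [write_image_set()]
#'
#' @param dir Directory containing `transfer.tif`, `saturation.tif` and
#'   `sidecar.json`.
#' @return An `image_set` object (images in counts; metadata reconstructed
#'   from the sidecar).
#' @export
read_image_set <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                            simplifyVector = TRUE)
  lay <- pad_layout(grid_rows = sc$layout$grid_rows,
                    grid_cols = sc$layout$grid_cols,
                    pad_size_px = sc$layout$pad_size_px,
                    pitch_px = sc$layout$pitch_px,
                    image_shape = sc$layout$image_shape,
                    offset_px = sc$layout$offset_px,
                    pad_conditions = as.data.frame(sc$layout$pad_conditions))
  truth <- ground_truth(
    lay,
    protein_density = sc$truth$protein_density,
    transfer_probability = sc$truth$transfer_probability,
    background_mean = sc$truth$background_mean,
    background_sd = sc$truth$background_sd,
    multiplicative_noise_cv = sc$truth$multiplicative_noise_cv,
    read_noise_sd = sc$truth$read_noise_sd,
    inhom_amplitude = sc$truth$inhom_amplitude,
    inhom_correlation_px = sc$truth$inhom_correlation_px,
    seed = sc$seed)
  structure(list(
    transfer_image = tiff::readTIFF(file.path(dir, "transfer.tif")) * 65535,
    saturation_image = tiff::readTIFF(file.path(dir, "saturation.tif")) * 65535,
    metadata = list(seed = sc$seed, layout = lay, truth = truth,
                    channel = sc$channel)
  ), class = "image_set")
}
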