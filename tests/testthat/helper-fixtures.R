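# Shared fixture builders: everything is generated in code at test time.

# Single-pad layout on a 256x256 field (160 px pad, 48 px border).
single_pad_layout <- function(motif = "high", n_bp = 20L) {
  pad_layout(grid_rows = 1, grid_cols = 1, pad_size_px = 160,
             pitch_px = 160, image_shape = c(256, 256),
             offset_px = c(48, 48),
             pad_conditions = data.frame(row = 1L, col = 1L,
                                         motif_label = motif,
                                         reference_n_bp = as.integer(n_bp)))
}

# Noise-free ground truth (all noise terms zero, flat density field).
noise_free_truth <- function(layout, density = 10000, p = 0.5,
                             background_mean = 1500, seed = 1L) {
  ground_truth(layout, protein_density = density,
               transfer_probability = p,
               background_mean = background_mean, background_sd = 0,
               multiplicative_noise_cv = 0, read_noise_sd = 0,
               inhom_amplitude = 0, seed = seed)
}

# Wrap a plain matrix of NF values into an nf_image (unit denominator).
as_nf_image <- function(values) {
  compute_nf_image(values, matrix(1, nrow(values), ncol(values)),
                   min_denominator = 0.5)
}

# Minimal fitted nf_estimate for comparison tests.
make_estimate <- function(nf_mean, nf_sd, status = "fitted", pad_id = NA) {
  mfaq:::nf_estimate(pad_id = pad_id, nf_mean = nf_mean, nf_sd = nf_sd,
                     n_pixels = 1000L, status = status)
}

# The four printed condition estimates of the reference experiment.
paper_conditions <- function() {
  data.frame(
    motif_label = c("high", "low", "high", "low"),
    reference_n_bp = c(20L, 20L, 40L, 40L),
    nf_mean = c(0.65, 0.39, 0.32, 0.20),
    nf_sd = c(0.07, 0.15, 0.01, 0.02),
    status = "fitted", stringsAsFactors = FALSE)
}

# Independent trapezoid quadrature of the competing-hazards integral,
# written without any package internals: P(ref first) on a fine force grid.
trapezoid_ref_probability <- function(k0_s, fb_s, k0_r, fb_r, rate,
                                      f_hi, n_grid = 40001) {
  F <- seq(0, f_hi, length.out = n_grid)
  h_s <- k0_s * exp(F / fb_s)
  h_r <- k0_r * exp(F / fb_r)
  htot <- (h_s + h_r) / rate
  dF <- F[2] - F[1]
  cumhaz <- c(0, cumsum((htot[-1] + htot[-n_grid]) / 2 * dF))
  dens <- (h_r / rate) * exp(-cumhaz)
  sum((dens[-1] + dens[-n_grid]) / 2 * dF)
}
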