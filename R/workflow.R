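# Workflow commands tying the stages together: simulate a seeded image
# pair with rupture-model ground truth, quantify it into a per-pad NF
# table, and calibrate the table into base-pair units. Each command is a
# plain function; the inst/cli/mfa script exposes them on the shell.

#' Simulate an image pair from a configuration
#'
#' Computes each pad's ground-truth transfer probability from the rupture
#' competition (motifs without a sample bond transfer nothing), renders
#' the transfer/saturation pair, and writes the 16-bit TIFFs, the JSON
#' truth sidecar and the resolved YAML config into `outdir`. Identical
#' configs and seeds reproduce the output files byte for byte.
#'
#' @param config An `mfa_config` (see [default_config()]).
#' @param outdir Output directory.
#' @return Invisibly, a list with the written `paths`, the `image_set`
#'   and the per-pad `transfer_probability` vector.
#' @export
cmd_simulate <- function(config = default_config(), outdir) {
  layout <- config_layout(config)
  p <- transfer_probabilities(layout, config_sample_bonds(config),
                              config$rupture$per_bp, config_ramp(config))
  truth <- ground_truth(
    layout,
    protein_density = config$imaging$protein_density,
    transfer_probability = p,
    background_mean = config$imaging$background_mean,
    background_sd = config$imaging$background_sd,
    multiplicative_noise_cv = config$imaging$multiplicative_noise_cv,
    read_noise_sd = config$imaging$read_noise_sd,
    inhom_amplitude = config$imaging$inhom_amplitude,
    inhom_correlation_px = config$imaging$inhom_correlation_px,
    seed = config$seed)
  iset <- render_image_set(layout, truth)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_image_set(iset, outdir)
  cfg_path <- file.path(outdir, "config.yaml")
  write_config(config, cfg_path)
  message(sprintf("[simulate] seed %d: wrote %d-pad image pair to %s",
                  config$seed, nrow(layout$pad_conditions), outdir))
  invisible(list(paths = c(paths, config = cfg_path), image_set = iset,
                 transfer_probability = p))
}

#' Quantify an image pair into a per-pad NF table
#'
#' Reads the TIFF pair and its sidecar (or takes an in-memory
#' `image_set`), runs [quantify_image_set()], and writes `pads.csv`, the
#' NF image (`nf.tif`, 32-bit float, scaled by `nf_tiff_scale` recorded in
#' `nf_meta.json`), the validity mask (`nf_mask.tif`) and a JSON summary.
#'
#' @param input Directory written by [cmd_simulate()] (containing
#'   `transfer.tif`, `saturation.tif`, `sidecar.json`) or an `image_set`.
#' @param config An `mfa_config` supplying the pipeline thresholds.
#' @param outdir Output directory.
#' @return Invisibly, the [quantify_image_set()] result.
#' @export
cmd_quantify <- function(input, config = default_config(), outdir) {
  iset <- if (inherits(input, "image_set")) input else read_image_set(input)
  pl <- config$pipeline
  q <- quantify_image_set(iset, margin_px = pl$margin_px, bins = pl$bins,
                          min_pixels = pl$min_pixels, k_sigma = pl$k_sigma,
                          min_denominator = pl$min_denominator)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(q$pads, file.path(outdir, "pads.csv"), row.names = FALSE)
  # float TIFFs only hold [0,1]; store NF divided by a recorded scale
  vals <- q$nf_image$values
  vals[!q$nf_image$valid_mask] <- 0
  nf_scale <- max(2, ceiling(max(vals)))
  tiff::writeTIFF(vals / nf_scale, file.path(outdir, "nf.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(q$nf_image$valid_mask * 1, file.path(outdir, "nf_mask.tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(
    list(nf_tiff_scale = nf_scale,
         backgrounds = q$backgrounds,
         min_denominator = q$nf_image$provenance$min_denominator,
         thresholds = pl[c("margin_px", "bins", "min_pixels", "k_sigma")]),
    file.path(outdir, "nf_meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  message(sprintf(
    "[quantify] %d pads: %d fitted, %d zeroed, %d failed; backgrounds %.0f/%.0f counts",
    nrow(q$pads), sum(q$pads$status == "fitted"),
    sum(q$pads$status == "zeroed"), sum(q$pads$status == "failed"),
    q$backgrounds$transfer$mean, q$backgrounds$saturation$mean))
  invisible(q)
}

#' Calibrate a per-pad NF table into base-pair units
#'
#' Aggregates fitted pads per (motif, reference length) condition
#' (inverse-variance over replicate pads would overweight tight fits;
#' the plain mean of pad means and of pad sds is used), then runs both
#' [equivalent_bp_difference()] routes and the per-motif linear models.
#' Writes `calibration.json`.
#'
#' @param pads Per-pad data frame (as written to `pads.csv`) or the path
#'   to such a CSV.
#' @param outdir Optional output directory for `calibration.json`.
#' @return A list report: `conditions`, `models`, `matched_lengths`,
#'   `matched_pair`, `linear_model` (either may carry an `error` string
#'   when its preconditions fail).
#' @export
cmd_calibrate <- function(pads, outdir = NULL) {
  if (is.character(pads)) pads <- utils::read.csv(pads,
                                                  stringsAsFactors = FALSE)
  if (nrow(pads) == 0) stop("insufficient data: empty per-pad table")
  agg <- aggregate_conditions(pads)
  try_route <- function(method) tryCatch(
    equivalent_bp_difference(agg, method = method),
    error = function(e) list(error = conditionMessage(e)))
  mp <- try_route("matched_pair")
  lmr <- try_route("linear_model")
  fitted <- agg[agg$status == "fitted", ]
  models <- list()
  matched <- list()
  for (m in unique(fitted$motif_label)) {
    sub <- fitted[fitted$motif_label == m, ]
    if (length(unique(sub$reference_n_bp)) >= 2) {
      models[[m]] <- fit_linear_nf_model(sub, m)
      matched[[m]] <- tryCatch(matched_reference_length(models[[m]]),
                               error = function(e)
                                 list(error = conditionMessage(e)))
    }
  }
  report <- list(conditions = agg,
                 models = lapply(models, unclass),
                 matched_lengths = matched,
                 matched_pair = if (inherits(mp, "equivalent_bp_result"))
                   list(motif_a = mp$motif_a, motif_b = mp$motif_b,
                        delta_bp = mp$delta_bp,
                        pair = mp$pair) else mp,
                 linear_model = if (inherits(lmr, "equivalent_bp_result"))
                   list(motif_a = lmr$motif_a, motif_b = lmr$motif_b,
                        delta_bp = lmr$delta_bp) else lmr)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outdir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  if (inherits(mp, "equivalent_bp_result"))
    message(sprintf(
      "[calibrate] matched pair %s vs %s: delta = %d bp",
      mp$motif_a, mp$motif_b, mp$delta_bp))
  report
}

# Average replicate pads into one row per (motif, reference length)
# condition; a condition is 'fitted' if any replicate pad was, 'zeroed'
# if all informative pads were zeroed.
aggregate_conditions <- function(pads) {
  key <- interaction(pads$motif_label, pads$reference_n_bp, drop = TRUE)
  rows <- lapply(split(pads, key), function(g) {
    f <- g[g$status == "fitted", ]
    if (nrow(f) > 0)
      data.frame(motif_label = g$motif_label[1],
                 reference_n_bp = g$reference_n_bp[1],
                 nf_mean = mean(f$nf_mean), nf_sd = mean(f$nf_sd),
                 n_pixels = sum(f$n_pixels), n_pads = nrow(g),
                 status = "fitted", stringsAsFactors = FALSE)
    else
      data.frame(motif_label = g$motif_label[1],
                 reference_n_bp = g$reference_n_bp[1],
                 nf_mean = 0, nf_sd = NA_real_,
                 n_pixels = sum(g$n_pixels), n_pads = nrow(g),
                 status = if (any(g$status == "zeroed")) "zeroed"
                          else "failed",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$motif_label, out$reference_n_bp), ]
}

#' Run the full pipeline from one configuration
#'
#' simulate -> quantify -> calibrate, writing all outputs under `outdir`
#' (`images/`, `quantify/`, `calibrate/`).
#'
#' @param config An `mfa_config`.
#' @param outdir Run directory.
#' @return Invisibly, a list with `simulate`, `quantify` and `calibrate`
#'   results.
#' @export
run_all <- function(config = default_config(), outdir) {
  sim <- cmd_simulate(config, file.path(outdir, "images"))
  q <- cmd_quantify(sim$image_set, config, file.path(outdir, "quantify"))
  cal <- cmd_calibrate(q$pads, file.path(outdir, "calibrate"))
  invisible(list(simulate = sim, quantify = q, calibrate = cal))
}
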