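# Workflow commands: simulate -> quantify -> calibrate round trips,
# byte-for-byte reproducibility, and the shell entry point.

test_that("cmd_simulate writes a complete, seeded image pair", {
  cfg <- default_config(seed = 7L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(cmd_simulate(cfg, d1))
  suppressMessages(cmd_simulate(cfg, d2))
  for (f in c("transfer.tif", "saturation.tif", "sidecar.json",
              "config.yaml")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  sc <- jsonlite::read_json(file.path(d1, "sidecar.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(sc$layout$pad_conditions), 16)
  # the default conditions include no-binding pads, flagged in the truth
  expect_gt(length(sc$truth$no_binding_pads), 0)
})

test_that("quantification recovers the sidecar ground truth", {
  cfg <- default_config(seed = 5L)
  dir <- withr::local_tempdir()
  sim <- suppressMessages(cmd_simulate(cfg, dir))
  q <- suppressMessages(cmd_quantify(dir, cfg, file.path(dir, "out")))
  expect_true(file.exists(file.path(dir, "out", "pads.csv")))
  expect_true(file.exists(file.path(dir, "out", "nf.tif")))
  pads <- utils::read.csv(file.path(dir, "out", "pads.csv"))
  truth_p <- sim$transfer_probability
  fitted <- pads$status == "fitted"
  expect_true(all(abs(pads$nf_mean[fitted] - truth_p[fitted]) < 0.02))
  expect_true(all(pads$status[truth_p == 0] == "zeroed"))
  # NF TIFF round-trips through its recorded scale
  meta <- jsonlite::read_json(file.path(dir, "out", "nf_meta.json"),
                              simplifyVector = TRUE)
  nf_back <- tiff::readTIFF(file.path(dir, "out", "nf.tif")) *
    meta$nf_tiff_scale
  vals <- q$nf_image$values
  vals[!q$nf_image$valid_mask] <- 0
  expect_equal(nf_back, vals, tolerance = 1e-6)
})

test_that("a noise-free half-transfer field quantifies to NF 0.5 on every pad", {
  lay <- pad_layout()
  iset <- render_image_set(lay, noise_free_truth(lay, density = 10000,
                                                 p = 0.5, seed = 2L))
  q <- suppressMessages(cmd_quantify(iset, default_config(),
                                     withr::local_tempdir()))
  expect_true(all(q$pads$status == "fitted"))
  expect_true(all(abs(q$pads$nf_mean - 0.5) < 1e-9))
})

test_that("an all-background transfer image zeroes every pad", {
  lay <- pad_layout()
  tr <- ground_truth(lay, transfer_probability = 0, background_sd = 50,
                     multiplicative_noise_cv = 0.05, read_noise_sd = 50,
                     seed = 13L)
  q <- suppressMessages(cmd_quantify(render_image_set(lay, tr),
                                     default_config(),
                                     withr::local_tempdir()))
  expect_true(all(q$pads$status == "zeroed"))
  expect_true(all(q$pads$nf_mean == 0))
})

test_that("calibration from a per-pad CSV reproduces the 20 bp interpretation", {
  csv <- file.path(withr::local_tempdir(), "pads.csv")
  tab <- paper_conditions()
  tab$pad_id <- sprintf("1-%d", seq_len(nrow(tab)))
  tab$n_pixels <- 10000L
  utils::write.csv(tab, csv, row.names = FALSE)
  rep <- suppressMessages(cmd_calibrate(csv))
  expect_equal(rep$matched_pair$delta_bp, 20)
  expect_lt(abs(rep$linear_model$delta_bp - 20.67), 0.01)
  # one reference length only: matched_pair attempted, linear_model errors
  one <- tab[tab$reference_n_bp == 20, ]
  utils::write.csv(one, csv, row.names = FALSE)
  rep1 <- suppressMessages(cmd_calibrate(csv))
  expect_true(is.character(rep1$linear_model$error))
  expect_false(is.null(rep1$matched_pair))
  # empty table
  utils::write.csv(tab[0, ], csv, row.names = FALSE)
  expect_error(suppressMessages(cmd_calibrate(csv)), "insufficient data")
})

test_that("the full default run reproduces the assay's headline numbers", {
  res <- suppressMessages(run_all(default_config(seed = 7L),
                                  withr::local_tempdir()))
  agg <- res$calibrate$conditions
  fitted <- agg[agg$status == "fitted", ]
  expected <- c(high.20 = 0.65, high.40 = 0.32, low.20 = 0.39, low.40 = 0.20)
  got <- fitted$nf_mean[match(
    names(expected),
    paste(fitted$motif_label, fitted$reference_n_bp, sep = "."))]
  expect_true(all(abs(got - expected) < 0.03))
  expect_equal(res$calibrate$matched_pair$delta_bp, 20)
  expect_lt(abs(res$calibrate$linear_model$delta_bp -
                  res$calibrate$matched_pair$delta_bp), 2)
  # zeroed no-binding conditions are reported with NF 0, never fitted
  zeroed <- agg[agg$motif_label == "no", ]
  expect_true(all(zeroed$status == "zeroed"))
  expect_true(all(zeroed$nf_mean == 0))
})

test_that("rerunning a config and seed reproduces all text outputs byte for byte", {
  cfg <- default_config(seed = 23L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(run_all(cfg, d1))
  suppressMessages(run_all(cfg, d2))
  rel <- c("images/transfer.tif", "images/saturation.tif",
           "images/sidecar.json", "quantify/pads.csv",
           "quantify/nf_meta.json", "calibrate/calibration.json")
  for (f in rel)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("the shell entry point drives the pipeline", {
  cli <- system.file("cli", "mfa", package = "mfaq")
  expect_true(nzchar(cli))
  env <- c(paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
  # no arguments: usage error, exit code 2
  code <- suppressWarnings(system2("Rscript", cli, stdout = FALSE,
                                   stderr = FALSE, env = env))
  expect_equal(code, 2)
  out <- file.path(withr::local_tempdir(), "run")
  code <- suppressWarnings(system2(
    "Rscript", c(cli, "simulate", "--outdir", out, "--seed", "3"),
    stdout = FALSE, stderr = FALSE, env = env))
  expect_equal(code, 0)
  expect_true(file.exists(file.path(out, "transfer.tif")))
})
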