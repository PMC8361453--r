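test_that("png round trip preserves intensities to quantization accuracy", {
  ph <- make_phantom(phantom_spec(height = 32, width = 32, seed = 1))
  noisy <- add_noise(ph$image, noise_spec("gaussian", 0.1, seed = 1))
  p <- file.path(tempdir(), "img.png")
  save_image(noisy, p)
  back <- load_image(p)
  expect_equal(dim(back), dim(noisy))
  expect_lte(max(abs(back - noisy)), 1 / 255)
  # all-white 8-bit png loads as all 1.0
  save_image(matrix(1, 8, 8), p)
  expect_equal(load_image(p), matrix(1, 8, 8))
})

test_that("label maps survive a png round trip verbatim", {
  ph <- make_phantom(phantom_spec(height = 24, width = 24, seed = 2))
  p <- file.path(tempdir(), "lab.png")
  save_label_map(ph$labels, p)
  expect_identical(load_label_map(p), ph$labels + 0L)
})

test_that("tiff images load on the unit scale", {
  p <- file.path(tempdir(), "img.tiff")
  img <- make_phantom(phantom_spec(height = 16, width = 16, seed = 3))$image
  tiff::writeTIFF(img, p)
  expect_lte(max(abs(load_image(p) - img)), 1 / 255)
})

test_that("nifti volumes require a slice selection and load slice-wise", {
  p <- file.path(tempdir(), "vol.nii.gz")
  vol <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  RNifti::writeNifti(RNifti::asNifti(vol), p)
  expect_error(load_image(p), class = "fuzzyseg_input_error")
  sl <- load_image(p, slice = 2)
  expect_equal(dim(sl), c(16L, 16L))
  expect_true(all(sl >= 0 & sl <= 1))
  expect_error(load_image("nope.png"), class = "fuzzyseg_input_error")
  expect_error(load_image(file.path(tempdir(), "img.xyz")), class = "fuzzyseg_input_error")
})

test_that("memberships round trip through csv text", {
  set.seed(5)
  U <- matrix(stats::runif(3 * 20), 3, 20); U <- sweep(U, 2, colSums(U), "/")
  p <- file.path(tempdir(), "u.csv")
  save_memberships(U, p)
  expect_equal(unname(load_memberships(p)), unname(U), tolerance = 1e-12)
})

test_that("the pipeline produces one record per noise level and seed with a 4-row aggregate", {
  cfg <- pipeline_config(
    phantom = phantom_spec(height = 24, width = 24, seed = 1),
    diffusion = diffusion_config(n_iter = 5),
    fcm = fcm_config(3, max_iter = 40),
    noise = lapply(c(0.1, 0.2, 0.3, 0.4), function(d) noise_spec("salt_pepper", d)),
    seeds = c(1L, 2L, 3L, 4L, 5L),
    method = "fcm_s")
  recs <- run_pipeline(cfg)
  expect_length(recs, 20)
  agg <- aggregate_records(recs)
  expect_equal(nrow(agg), 4)
  expect_equal(agg$n_runs, rep(5L, 4))
})

test_that("a zero-noise run on the default phantom is segmented near-perfectly", {
  cfg <- pipeline_config(
    diffusion = diffusion_config(n_iter = 5),
    fcm = fcm_config(3),
    noise = list(), seeds = 1L, method = "sipmfcm")
  rec <- run_pipeline(cfg)[[1]]
  expect_true(all(rec$report$dsc_per_class >= 0.99))
})

test_that("re-running an identical pipeline config writes byte-identical reports", {
  cfg_of <- function(dir) pipeline_config(
    phantom = phantom_spec(height = 20, width = 20, seed = 4),
    diffusion = diffusion_config(n_iter = 3),
    fcm = fcm_config(3, max_iter = 30),
    noise = list(noise_spec("gaussian", 0.05)),
    seeds = c(1L, 2L), method = "sipmfcm", out_dir = dir)
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  run_pipeline(cfg_of(d1)); run_pipeline(cfg_of(d2))
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = paste("bytes of", f))
  }
})

test_that("run records survive a json round trip", {
  dir <- file.path(tempdir(), "runC")
  cfg <- pipeline_config(
    phantom = phantom_spec(height = 20, width = 20, seed = 5),
    diffusion = diffusion_config(n_iter = 3),
    fcm = fcm_config(3, max_iter = 30),
    noise = list(noise_spec("salt_pepper", 0.2)),
    seeds = 3L, method = "fcm", out_dir = dir)
  rec <- run_pipeline(cfg)[[1]]
  back <- read_run_record(file.path(dir, "run_001.json"))
  expect_equal(back$seed, rec$seed)
  expect_equal(back$config_hash, rec$config_hash)
  expect_equal(back$centers, rec$centers, tolerance = 1e-12)
  expect_equal(back$objective_history, rec$objective_history, tolerance = 1e-12)
  expect_equal(unname(unlist(back$report$dsc_per_class)),
               unname(unlist(rec$report$dsc_per_class)), tolerance = 1e-12)
  expect_equal(back$report$v_pc, rec$report$v_pc, tolerance = 1e-12)
})

test_that("the aggregate csv has the documented fixed column set", {
  dir <- file.path(tempdir(), "runD")
  cfg <- pipeline_config(
    phantom = phantom_spec(height = 20, width = 20, seed = 6),
    diffusion = diffusion_config(n_iter = 2),
    fcm = fcm_config(3, max_iter = 20),
    noise = list(noise_spec("gaussian", 0.05)),
    seeds = c(1L, 2L), method = "fcm", out_dir = dir)
  run_pipeline(cfg)
  agg <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_identical(names(agg),
    c("noise", "n_runs", "dsc_mean", "dsc_sd", "jaccard_mean", "jaccard_sd",
      "v_pc_mean", "v_pc_sd", "v_pe_mean", "v_pe_sd", "psnr_mean", "psnr_sd"))
})

test_that("aggregate statistics equal recomputation from the per-run jsons", {
  dir <- file.path(tempdir(), "runE")
  cfg <- pipeline_config(
    phantom = phantom_spec(height = 20, width = 20, seed = 7),
    diffusion = diffusion_config(n_iter = 2),
    fcm = fcm_config(3, max_iter = 30),
    noise = list(noise_spec("salt_pepper", 0.1)),
    seeds = c(1L, 2L, 3L), method = "fcm_s", out_dir = dir)
  run_pipeline(cfg)
  reloaded <- lapply(list.files(dir, pattern = "^run_.*json$", full.names = TRUE),
                     read_run_record)
  agg2 <- aggregate_records(reloaded)
  agg1 <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(agg1$dsc_mean, agg2$dsc_mean, tolerance = 1e-10)
  expect_equal(agg1$v_pe_sd, agg2$v_pe_sd, tolerance = 1e-10)
})

test_that("inconsistent cluster counts are rejected at configuration time", {
  expect_error(pipeline_config(phantom = phantom_spec(), fcm = fcm_config(4)),
               class = "fuzzyseg_config_error")
})

test_that("the command-line front end generates a phantom from a shell invocation", {
  cli <- system.file("cli", "fuzzyseg.R", package = "fuzzyseg")
  expect_true(nzchar(cli))
  dir <- tempfile("cli"); dir.create(dir)
  out <- file.path(dir, "img.png"); tr <- file.path(dir, "truth.png")
  res <- system2(file.path(R.home("bin"), "Rscript"), c(cli, "phantom",
                 "--size", "32", "--classes", "3", "--seed", "5",
                 "--out", out, "--truth", tr),
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out) && file.exists(tr))
  expect_setequal(unique(as.vector(load_label_map(tr))), 0:2)
})
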