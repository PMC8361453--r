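#' Configure an end-to-end segmentation experiment
#'
#' The pipeline reproduces the method's experiment design at desk scale:
#' for every noise specification and every replicate seed, a phantom (or a
#' supplied image) is corrupted, denoised by Perona-Malik diffusion,
#' segmented, spatially fused, defuzzified, and scored against the ground
#' truth.
#'
#' @param phantom a \code{\link{phantom_spec}} (or NULL when \code{input}
#'   is given).
#' @param input optional path to a real input image (with optional
#'   \code{truth} label-map path).
#' @param truth optional path to a ground-truth label PNG for \code{input}.
#' @param diffusion a \code{\link{diffusion_config}}.
#' @param fcm an \code{\link{fcm_config}}; when a phantom with truth is
#'   used, \code{n_clusters} must equal the number of phantom classes.
#' @param noise list of \code{\link{noise_spec}}s (may be empty for a
#'   clean run); each is re-seeded per replicate.
#' @param seeds integer vector of replicate seeds.
#' @param method \code{"fcm"}, \code{"fcm_s"} or \code{"sipmfcm"}.
#' @param fuse apply spatial membership fusion after convergence.
#' @param out_dir optional output directory for per-run JSON reports and
#'   the aggregate CSV.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            input = NULL, truth = NULL,
                            diffusion = diffusion_config(),
                            fcm = fcm_config(n_clusters = 3),
                            noise = list(),
                            seeds = 1L,
                            method = c("sipmfcm", "fcm", "fcm_s"),
                            fuse = TRUE,
                            out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(input)) {
    if (!inherits(phantom, "phantom_spec")) stop_config("phantom must be a phantom_spec")
    if (fcm$n_clusters != length(phantom$class_means))
      stop_config("n_clusters (%d) must equal the number of phantom classes (%d)",
                  fcm$n_clusters, length(phantom$class_means))
  }
  if (!inherits(diffusion, "diffusion_config")) stop_config("diffusion must be a diffusion_config")
  if (!inherits(fcm, "fcm_config")) stop_config("fcm must be an fcm_config")
  if (inherits(noise, "noise_spec")) noise <- list(noise)
  if (!all(vapply(noise, inherits, logical(1), "noise_spec")))
    stop_config("noise must be a list of noise_spec objects")
  structure(list(phantom = phantom, input = input, truth = truth,
                 diffusion = diffusion, fcm = fcm, noise = noise,
                 seeds = as.integer(seeds), method = method, fuse = fuse,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full segmentation pipeline
#'
#' For each noise level x replicate seed: generate or load the input,
#' corrupt it, denoise with Perona-Malik diffusion, fit the configured
#' clustering method, optionally fuse memberships with the spatial
#' function, defuzzify, and evaluate. With \code{out_dir} set, one JSON
#' report per run plus an aggregate CSV are written.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return list of \code{run_record} objects (invisibly also written to
#'   disk when \code{out_dir} is set).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop_config("cfg must be a pipeline_config")
  if (is.null(cfg$input)) {
    ph <- make_phantom(cfg$phantom)
    clean <- ph$image; truth <- ph$labels
  } else {
    clean <- load_image(cfg$input)
    truth <- if (!is.null(cfg$truth)) load_label_map(cfg$truth) else NULL
  }
  noise_list <- if (length(cfg$noise) == 0) list(NULL) else cfg$noise
  records <- list()
  for (nz in noise_list) {
    for (seed in cfg$seeds) {
      rec <- run_one(cfg, clean, truth, nz, seed)
      records[[length(records) + 1L]] <- rec
    }
  }
  if (!is.null(cfg$out_dir)) write_report(records, cfg$out_dir)
  records
}

run_one <- function(cfg, clean, truth, nz, seed) {
  t0 <- proc.time()[["elapsed"]]
  noisy <- clean
  if (!is.null(nz)) {
    nz$seed <- as.integer(seed)
    noisy <- add_noise(clean, nz)
  }
  denoised <- pm_denoise(noisy, cfg$diffusion)
  fc <- cfg$fcm
  fc$seed <- as.integer(seed)
  fit <- switch(cfg$method,
                fcm = fcm_fit(denoised, fc),
                fcm_s = fcm_s_fit(denoised, fc),
                sipmfcm = sipmfcm_fit(denoised, fc))
  U <- fit$memberships
  if (cfg$fuse) {
    S <- spatial_function(U, dim(clean), fc$neighborhood)
    U <- fuse_spatial_membership(U, S, fc$fuse_p, fc$fuse_q)
  }
  labels <- defuzzify(U, dim(clean))
  report <- validity_report(U = U, pred = labels, truth = truth,
                            clean = clean, test = denoised)
  structure(list(
    config_hash = config_hash(cfg),
    seed = as.integer(seed),
    method = cfg$method,
    noise = if (is.null(nz)) list(kind = "none", level = 0)
            else list(kind = nz$kind, level = nz$level),
    centers = fit$centers,
    n_iter_run = fit$n_iter_run,
    converged = fit$converged,
    objective_history = fit$objective_history,
    psnr_noisy_db = if (is.null(nz)) Inf else psnr(clean, noisy),
    report = unclass(report),
    wall_time_s = proc.time()[["elapsed"]] - t0),
    class = "run_record")
}

# Deterministic config fingerprint: md5 of the deparsed configuration.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)[setdiff(names(cfg), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Write per-run JSON reports and an aggregate CSV
#'
#' Each run becomes \code{run_<i>.json} (schema version 1, lossless:
#' \code{\link{read_run_record}} reloads it); the aggregate
#' \code{summary.csv} has one row per noise condition with mean and sd of
#' mean Dice, mean Jaccard, V_pc, V_pe and denoised PSNR across seeds.
#'
#' @param records list of \code{run_record}s.
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_report <- function(records, dir) {
  if (length(records) == 0) stop_input("no records to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop_input("directory not writable: %s", dir)
  paths <- character(0)
  for (i in seq_along(records)) {
    p <- file.path(dir, sprintf("run_%03d.json", i))
    rec <- unclass(records[[i]])
    rec$wall_time_s <- NULL  # informational only; kept out so reports are byte-reproducible
    rec$schema_version <- 1L
    jsonlite::write_json(rec, p, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "string")
    paths <- c(paths, p)
  }
  agg <- aggregate_records(records)
  csv <- file.path(dir, "summary.csv")
  utils::write.csv(agg, csv, row.names = FALSE)
  invisible(c(paths, csv))
}

#' Reload a run record written by \code{\link{write_report}}
#' @param path a run_*.json path.
#' @return a \code{run_record}.
#' @export
read_run_record <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$schema_version <- NULL
  for (f in c("psnr_noisy_db"))
    if (is.character(rec[[f]])) rec[[f]] <- Inf
  if (is.character(rec$report$psnr_db)) rec$report$psnr_db <- Inf
  structure(rec, class = "run_record")
}

#' Aggregate run records into a per-noise-condition summary table
#' @param records list of \code{run_record}s.
#' @return data.frame, one row per noise condition.
#' @export
aggregate_records <- function(records) {
  key <- vapply(records, function(r) sprintf("%s:%g", r$noise$kind, r$noise$level),
                character(1))
  rows <- lapply(unique(key), function(k) {
    rs <- records[key == k]
    pull <- function(f) vapply(rs, function(r) {
      v <- f(r); if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
    }, numeric(1))
    mdsc <- pull(function(r) mean(r$report$dsc_per_class))
    mjac <- pull(function(r) mean(r$report$jaccard_per_class))
    vpc <- pull(function(r) r$report$v_pc)
    vpe <- pull(function(r) r$report$v_pe)
    ps <- pull(function(r) r$report$psnr_db)
    data.frame(noise = k, n_runs = length(rs),
               dsc_mean = mean(mdsc), dsc_sd = stats::sd(mdsc),
               jaccard_mean = mean(mjac), jaccard_sd = stats::sd(mjac),
               v_pc_mean = mean(vpc), v_pc_sd = stats::sd(vpc),
               v_pe_mean = mean(vpe), v_pe_sd = stats::sd(vpe),
               psnr_mean = mean(ps), psnr_sd = stats::sd(ps))
  })
  do.call(rbind, rows)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record: %s, noise %s:%g, seed %d>\n",
              x$method, x$noise$kind, x$noise$level, x$seed))
  cat(sprintf("  mean DSC = %.4f, V_pc = %.4f, V_pe = %.4f\n",
              mean(x$report$dsc_per_class), x$report$v_pc, x$report$v_pe))
  invisible(x)
}
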