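#' Pipeline run configuration
#'
#' Assembles and validates the configuration of an end-to-end run. A
#' configuration without an explicit seed is refused: every stochastic
#' stage must be reproducible.
#'
#' @param seed Integer master seed (required).
#' @param period `"2-month"` or `"1-month"` treatment cohort.
#' @param cine_matrix,cine_fov_mm,cine_frames Cine grid for the vasomotor
#'   stage (defaults are a desk-scale 128 x 128 x 16 grid, 5 frames).
#' @param branch_slice 0-based bifurcation slice of the cine phantom.
#' @param vfa_matrix,vfa_fov_mm VFA grid for the permeability stage.
#' @param snr Signal-to-noise ratio (blood signal over noise sigma) of
#'   both simulated acquisitions.
#' @param segmentation_fraction Lumen threshold position (see
#'   [segment_lumen_slice()]).
#' @param npx50_threshold Relative T1 change cutoff.
#' @param rim_px Perivascular rim thickness, voxels.
#' @param out_dir Optional output directory for [write_results()] and
#'   stage logs.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(seed, period = "2-month",
                       cine_matrix = c(128, 128, 16),
                       cine_fov_mm = c(30, 30, 30 * 16 / 96),
                       cine_frames = 5L, branch_slice = 10L,
                       vfa_matrix = c(96, 80, 8), vfa_fov_mm = c(30, 30, 4),
                       snr = 40, segmentation_fraction = 0.5,
                       npx50_threshold = 0.5, rim_px = 2L, out_dir = NULL) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_ep("configuration has no seed: refusing to run a non-reproducible pipeline")
  cfg <- list(seed = as.integer(seed), period = period,
              cine_matrix = cine_matrix, cine_fov_mm = cine_fov_mm,
              cine_frames = as.integer(cine_frames),
              branch_slice = as.integer(branch_slice),
              vfa_matrix = vfa_matrix, vfa_fov_mm = vfa_fov_mm,
              snr = snr, segmentation_fraction = segmentation_fraction,
              npx50_threshold = npx50_threshold, rim_px = as.integer(rim_px),
              out_dir = out_dir)
  if (!period %in% c("2-month", "1-month"))
    stop_ep("'period' must be \"2-month\" or \"1-month\"")
  if (snr <= 0) stop_ep("'snr' must be > 0")
  if (segmentation_fraction <= 0 || segmentation_fraction >= 1)
    stop_ep("'segmentation_fraction' must lie in (0, 1)")
  if (npx50_threshold <= 0 || npx50_threshold >= 1)
    stop_ep("'npx50_threshold' must lie in (0, 1)")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML round-trip is lossless for all configuration fields; reading
#' re-validates through [run_config()], so a file without a seed is
#' rejected.
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config`: a `run_config`; `write_run_config`: the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_ep("no such config file: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed))
    stop_ep("configuration has no seed: refusing to run a non-reproducible pipeline")
  raw$out_dir <- raw$out_dir %||% NULL
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# locate a seed point inside the lumen: argmax of a 3x3-smoothed slice
find_seed_point <- function(slice_2d) {
  k <- matrix(1 / 9, 3, 3)
  sm <- EBImage::imageData(EBImage::filter2(EBImage::Image(slice_2d), k))
  ij <- which(sm == max(sm), arr.ind = TRUE)[1, ]
  as.numeric(ij) - 1
}

#' Run the full endothelial profiling pipeline
#'
#' End-to-end, per-animal simulation and analysis mirroring the study
#' design: for every animal of the three groups, (1) simulate a pre/post
#' acetylcholine cine pair whose ground-truth dilation encodes the
#' group-level response plus animal-level variation and measure the
#' vasomotor response by segmentation + volumetry; (2) simulate the
#' pre/post-contrast VFA series with an animal-specific number of leaking
#' rim voxels, fit both T1 maps and compute Npx50; (3) simulate the plasma
#' panel; (4) join everything into the cohort report (group summaries,
#' percent-change tables, the five function-biochemistry correlations).
#' Re-running with the same configuration is bit-identical.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return A list with `profile` (a `cohort_profile`), `imaging` (the
#'   measured per-animal endpoints), `panel`, and `log` (stage records).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  logs <- list()
  log_stage <- function(stage, ...) {
    entry <- c(list(stage = stage), list(...))
    logs[[length(logs) + 1L]] <<- entry
    entry
  }

  fn_proto <- imaging_protocol(6.4, 1.4, config$cine_fov_mm, config$cine_matrix,
                               30, n_frames = config$cine_frames,
                               label = "pipeline cine")
  vfa_proto <- imaging_protocol(10, 1.1, config$vfa_fov_mm, config$vfa_matrix,
                                c(2, 4, 6, 8, 14, 20, 30, 50),
                                n_frames = 1L, label = "pipeline VFA")
  tissue <- tissue_params()

  gt <- simulate_study_cohort(config$period, config$seed)
  panel <- gt$panel
  truth <- gt$imaging      # per-animal ground-truth endpoints to encode
  log_stage("simulate_cohort", seed = config$seed, period = config$period,
            n_animals = nrow(truth))

  cine_sigma <- tissue$cine_intensity[["blood"]] / config$snr
  vfa_sigma <- max(tissue$m0) / config$snr
  seeds <- derive_seeds(config$seed, nrow(truth), salt = 11L)
  dia_frame <- max(0L, min(config$cine_frames - 1L, 3L))

  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- 1 + truth$bca_volume_change_pct[i] / 100
    geom <- default_geometry(fn_proto, radius_mm = 1.21, taper_per_slice = 0.016,
                             branch_slice = config$branch_slice,
                             dilation_factor = d, diastolic_frame = dia_frame)
    tis <- tissue; tis$noise_sigma <- cine_sigma
    cines <- simulate_cine(geom, tis, fn_proto, seed = seeds[i])
    seed_pt <- find_seed_point(cines$pre$intensities[, , 2, 1])
    vr <- measure_vasomotion(cines$pre, cines$post, seed_pt,
                             fraction = config$segmentation_fraction)

    tis_vfa <- tissue; tis_vfa$noise_sigma <- vfa_sigma
    ph <- simulate_permeability_phantom(truth$npx50[i], tis_vfa, vfa_proto,
                                        seed = seeds[i] + 1,
                                        rim_px = config$rim_px)
    fit_pre <- fit_t1_map(ph$pre, mask = ph$labels > 0)
    fit_post <- fit_t1_map(ph$post, mask = ph$labels > 0)
    pr <- compute_npx50(fit_pre, fit_post, ph$rim_mask,
                        threshold = config$npx50_threshold)
    rows[[i]] <- data.frame(
      animal_id = truth$animal_id[i], group = truth$group[i],
      bca_volume_change_pct = vr$percent_change, npx50 = pr$npx50,
      stringsAsFactors = FALSE)
    log_stage("animal", animal_id = truth$animal_id[i], seed = seeds[i],
              diastolic_frame = vr$diastolic_frame_pre,
              npx50_excluded = pr$excluded)
  }
  imaging <- do.call(rbind, rows)
  log_stage("vasomotion", segmentation_fraction = config$segmentation_fraction)
  log_stage("permeability", threshold = config$npx50_threshold,
            rim_px = config$rim_px)

  profile <- profile_cohort(imaging, panel)
  log_stage("report", reference_group = profile$reference_group)

  if (!is.null(config$out_dir)) {
    write_results(profile, config$out_dir,
                  extra = list(seed = config$seed, period = config$period))
    con <- file(file.path(config$out_dir, "stages.jsonl"), "w")
    for (entry in logs)
      writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
    close(con)
    write_plasma_panel(panel, file.path(config$out_dir, "plasma_panel.csv"))
  }
  list(profile = profile, imaging = imaging, panel = panel, log = logs)
}
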