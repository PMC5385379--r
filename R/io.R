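check_pixdim <- function(img, path) {
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop_ep("NIfTI file '%s' has no valid voxel-size header", path)
  pd
}

#' Write / read a cine volume as NIfTI
#'
#' The 4D intensity stack is stored as double-precision NIfTI (voxel size
#' in the header, frame-major fourth dimension) with a JSON sidecar
#' (`<file>.json`) carrying the protocol. Round-trips are bit-identical
#' and preserve voxel sizes to well below 1e-6 mm.
#'
#' @param cine A `cine_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_cine`: the path, invisibly. `read_cine`: a
#'   `cine_volume`.
#' @export
write_cine <- function(cine, path) {
  stopifnot(inherits(cine, "cine_volume"))
  img <- RNifti::asNifti(cine$intensities)
  RNifti::pixdim(img) <- c(cine$voxel_mm, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  p <- cine$protocol
  jsonlite::write_json(
    list(tr_ms = p$tr_ms, te_ms = p$te_ms, fov_mm = p$fov_mm,
         matrix = p$matrix, flip_angles_deg = p$flip_angles_deg,
         n_frames = p$n_frames, label = p$label, state = cine$state),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine
#' @export
read_cine <- function(path) {
  img <- RNifti::readNifti(path)
  check_pixdim(img, path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_ep("missing protocol sidecar '%s'", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  proto <- imaging_protocol(meta$tr_ms, meta$te_ms, meta$fov_mm, meta$matrix,
                            meta$flip_angles_deg, meta$n_frames, meta$label)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (!identical(dim(arr)[1:3], as.integer(proto$matrix)))
    stop_ep("volume shape %s does not match sidecar matrix %s",
            paste(dim(arr)[1:3], collapse = "x"),
            paste(proto$matrix, collapse = "x"))
  new_cine_volume(arr, proto, meta$state %||% "pre")
}

#' Write / read a variable flip angle series
#'
#' One NIfTI volume per flip angle (`fa_<angle>.nii.gz`) plus a JSON
#' sidecar (`vfa.json`) listing the angles, TR, TE and grid. Reading
#' validates that the number of volumes matches the sidecar's angle list
#' and that all volumes share one shape.
#'
#' @param series A `vfa_series`.
#' @param dir Directory (created if needed).
#' @return `write_vfa_series`: `dir`, invisibly. `read_vfa_series`: a
#'   `vfa_series`.
#' @export
write_vfa_series <- function(series, dir) {
  stopifnot(inherits(series, "vfa_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- series$protocol
  for (a in seq_along(series$flip_angles_deg)) {
    img <- RNifti::asNifti(series$volumes[, , , a])
    RNifti::pixdim(img) <- p$voxel_mm
    RNifti::writeNifti(img, file.path(dir, sprintf("fa_%02d.nii.gz", a)),
                       datatype = "double")
  }
  jsonlite::write_json(
    list(flip_angles_deg = series$flip_angles_deg, tr_ms = p$tr_ms,
         te_ms = p$te_ms, fov_mm = p$fov_mm, matrix = p$matrix,
         ca_state = series$ca_state),
    file.path(dir, "vfa.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_vfa_series
#' @export
read_vfa_series <- function(dir) {
  side <- file.path(dir, "vfa.json")
  if (!file.exists(side)) stop_ep("missing sidecar '%s'", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^fa_[0-9]+\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) != length(meta$flip_angles_deg))
    stop_ep("sidecar lists %d flip angles but %d volumes found",
            length(meta$flip_angles_deg), length(files))
  vols <- lapply(files, function(f) {
    img <- RNifti::readNifti(f); check_pixdim(img, f)
    array(as.numeric(img), dim = dim(img))
  })
  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_ep("volumes have inconsistent shapes: %s",
            paste(unique(shapes), collapse = ", "))
  proto <- imaging_protocol(meta$tr_ms, meta$te_ms, meta$fov_mm, meta$matrix,
                            meta$flip_angles_deg, 1L, "VFA (read)")
  arr <- array(0, dim = c(dim(vols[[1]]), length(vols)))
  for (a in seq_along(vols)) arr[, , , a] <- vols[[a]]
  new_vfa_series(arr, meta$flip_angles_deg, proto, meta$ca_state %||% "pre")
}

#' Write / read T1 maps as NIfTI
#'
#' Writes the T1, M0 and fit-quality maps as `<prefix>_t1.nii.gz`,
#' `<prefix>_m0.nii.gz`, `<prefix>_r2.nii.gz` (failed pixels as NaN).
#'
#' @param map A `t1_map`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_t1_map <- function(map, prefix) {
  stopifnot(inherits(map, "t1_map"))
  for (part in c("t1", "m0", "r2")) {
    arr <- switch(part, t1 = map$t1_ms, m0 = map$m0, r2 = map$fit_quality)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- map$voxel_mm
    RNifti::writeNifti(img, sprintf("%s_%s.nii.gz", prefix, part),
                       datatype = "double")
  }
  invisible(prefix)
}

#' Write / read a plasma panel CSV
#'
#' Long-format CSV with columns `animal_id`, `group`, `analyte`,
#' `concentration`, `units`.
#'
#' @param panel Plasma panel data frame.
#' @param path CSV path.
#' @return `write_plasma_panel`: the path, invisibly;
#'   `read_plasma_panel`: the panel.
#' @export
write_plasma_panel <- function(panel, path) {
  check_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plasma_panel
#' @export
read_plasma_panel <- function(path) {
  if (!file.exists(path)) stop_ep("no such file: %s", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_panel(panel)
  panel
}

#' Write pipeline results to a directory
#'
#' Emits the cohort report as machine-readable files: `correlations.csv`,
#' `group_summary.csv`, `percent_change.csv`, `animals.csv` and a
#' `report.json` combining the scalar endpoints.
#'
#' @param profile A `cohort_profile`.
#' @param dir Output directory (created if needed).
#' @param extra Optional named list merged into `report.json`.
#' @return `dir`, invisibly.
#' @export
write_results <- function(profile, dir, extra = NULL) {
  stopifnot(inherits(profile, "cohort_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(profile$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(profile$group_summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(profile$percent_change, file.path(dir, "percent_change.csv"),
                   row.names = FALSE)
  utils::write.csv(profile$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  report <- list(
    reference_group = profile$reference_group,
    correlations = profile$correlations,
    group_tests = lapply(profile$group_tests, function(t)
      list(test = t$test, statistic = t$statistic, p_value = t$p_value)))
  jsonlite::write_json(c(report, extra), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
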