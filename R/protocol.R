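#' MR imaging protocol
#'
#' Container for the acquisition geometry and timing of a gradient-echo
#' protocol: repetition/echo time, field of view, acquisition matrix, the
#' flip angle(s) played out, and the number of reconstructed cardiac frames.
#' Voxel size is derived as `fov_mm / matrix`, element-wise.
#'
#' @param tr_ms Repetition time in ms.
#' @param te_ms Echo time in ms.
#' @param fov_mm Length-3 numeric, field of view in mm (row, column, slice
#'   directions).
#' @param matrix Length-3 integer, number of voxels along each axis.
#' @param flip_angles_deg Numeric vector of flip angles in degrees, strictly
#'   increasing when more than one; each in (0, 90].
#' @param n_frames Number of reconstructed cardiac frames (>= 1).
#' @param label Free-text protocol name.
#'
#' @return An object of class `imaging_protocol`: a list with the fields
#'   above plus `voxel_mm`.
#' @examples
#' p <- imaging_protocol(6.4, 1.4, c(30, 30, 5), c(256, 256, 30), 30, n_frames = 7)
#' p$voxel_mm
#' @export
imaging_protocol <- function(tr_ms, te_ms, fov_mm, matrix, flip_angles_deg,
                             n_frames = 1L, label = "custom") {
  check_scalar_pos(tr_ms, "tr_ms")
  check_scalar_pos(te_ms, "te_ms")
  if (length(fov_mm) != 3L || any(!is.finite(fov_mm)) || any(fov_mm <= 0))
    stop_ep("'fov_mm' must be 3 positive numbers")
  if (length(matrix) != 3L || any(matrix < 1) || any(matrix != round(matrix)))
    stop_ep("'matrix' must be 3 positive integers")
  if (length(flip_angles_deg) < 1L || any(flip_angles_deg <= 0) ||
      any(flip_angles_deg > 90))
    stop_ep("flip angles must lie in (0, 90] degrees")
  if (length(flip_angles_deg) > 1L && any(diff(flip_angles_deg) <= 0))
    stop_ep("flip angles must be strictly increasing")
  if (n_frames < 1L || n_frames != round(n_frames))
    stop_ep("'n_frames' must be an integer >= 1")
  structure(list(
    tr_ms = tr_ms, te_ms = te_ms,
    fov_mm = as.numeric(fov_mm), matrix = as.integer(matrix),
    flip_angles_deg = as.numeric(flip_angles_deg),
    n_frames = as.integer(n_frames),
    voxel_mm = as.numeric(fov_mm) / as.integer(matrix),
    label = label
  ), class = "imaging_protocol")
}

#' @export
print.imaging_protocol <- function(x, ...) {
  cat("<imaging_protocol>", x$label, "\n")
  cat(sprintf("  TR %.2f ms, TE %.2f ms\n", x$tr_ms, x$te_ms))
  cat(sprintf("  FOV %s mm, matrix %s (voxel %s mm)\n",
              paste(x$fov_mm, collapse = "x"),
              paste(x$matrix, collapse = "x"),
              paste(signif(x$voxel_mm, 4), collapse = "x")))
  cat(sprintf("  flip angle(s): %s deg; %d cardiac frame(s)\n",
              paste(x$flip_angles_deg, collapse = ", "), x$n_frames))
  invisible(x)
}

#' Study imaging protocols
#'
#' Presets mirroring the two 9.4 T acquisitions used for endothelial
#' profiling: a cine FLASH protocol for vasomotor (volume) assessment and a
#' multi-flip-angle spoiled gradient-echo protocol for T1 mapping /
#' permeability assessment.
#'
#' `protocol_function()`: TR 6.4 ms, TE 1.4 ms, FOV 30x30x5 mm, matrix
#' 256x256x30, flip angle 30 deg, 7 cardiac frames.
#'
#' `protocol_permeability()`: TR 10 ms, TE 1.1 ms, FOV 30x30x4 mm, matrix
#' 192x160x8, eight flip angles (2, 4, 6, 8, 14, 20, 30, 50 deg), one frame.
#'
#' @return An [imaging_protocol()].
#' @export
protocol_function <- function() {
  imaging_protocol(6.4, 1.4, c(30, 30, 5), c(256, 256, 30), 30,
                   n_frames = 7L, label = "endothelial function (cine FLASH)")
}

#' @rdname protocol_function
#' @export
protocol_permeability <- function() {
  imaging_protocol(10, 1.1, c(30, 30, 4), c(192, 160, 8),
                   c(2, 4, 6, 8, 14, 20, 30, 50),
                   n_frames = 1L, label = "endothelial permeability (VFA)")
}
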