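#' Straight-cylinder phantom geometry
#'
#' A single straight (optionally slanted/tapered) vessel spanning the whole
#' slice stack, with no branch. Useful for analytic-volume checks and for
#' the permeability phantom, where the analysed stack ends below the
#' bifurcation.
#'
#' @inheritParams default_geometry
#' @param slant_mm_per_slice,taper_per_slice As in [default_geometry()]
#'   (default 0: a true cylinder).
#' @return A [vessel_geometry()] without an effective branch.
#' @export
cylinder_geometry <- function(protocol, radius_mm = 1.0,
                              center_frac = c(0.5, 0.5),
                              slant_mm_per_slice = c(0, 0),
                              taper_per_slice = 0,
                              wall_thickness_mm = 0.12,
                              pulsation_amplitude = 0,
                              dilation_factor = 1,
                              diastolic_frame = 0L) {
  nz <- protocol$matrix[3]
  dz <- protocol$voxel_mm[3]
  npts <- max(2L * nz + 1L, 5L)            # oversampled along z
  s <- seq(0, nz - 1, length.out = npts)
  z <- s * dz
  cx <- center_frac[1] * protocol$fov_mm[1] + slant_mm_per_slice[1] * s
  cy <- center_frac[2] * protocol$fov_mm[2] + slant_mm_per_slice[2] * s
  r <- radius_mm * (1 - taper_per_slice * s)
  if (any(r <= 0)) stop_ep("taper removes the lumen before the last slice")
  vessel_geometry(
    centerline = cbind(cx, cy, z), radius_mm = r,
    branch_centerline = matrix(c(cx[2], cy[2], z[2]), 1L, 3L),  # degenerate
    branch_radius_mm = r[2] * 0.5, branch_at = 2L,
    wall_thickness_mm = wall_thickness_mm,
    pulsation_amplitude = pulsation_amplitude,
    dilation_factor = dilation_factor,
    diastolic_frame = diastolic_frame
  )
}

new_vfa_series <- function(volumes, flip_angles_deg, protocol,
                           ca_state = "pre", gt = list()) {
  structure(list(volumes = volumes, flip_angles_deg = flip_angles_deg,
                 protocol = protocol, ca_state = ca_state, gt = gt),
            class = "vfa_series")
}

#' @export
print.vfa_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<vfa_series> %s-contrast: %d x %d x %d voxels, %d flip angles (%s deg)\n",
              x$ca_state, d[1], d[2], d[3], d[4],
              paste(x$flip_angles_deg, collapse = ", ")))
  invisible(x)
}

#' Simulate a variable flip angle series from a label volume
#'
#' Forward-simulates the multi-flip-angle spoiled gradient-echo
#' acquisition: each voxel's noiseless intensity is the [spgr_signal()] of
#' its compartment's (m0, T1) at every flip angle, and Rician noise of
#' scale `tissue$noise_sigma` is applied independently per voxel and angle.
#'
#' In the post-contrast state, blood uses its post-contrast T1 and exactly
#' `round(leak_fraction * n_rim)` perivascular-rim voxels — chosen
#' reproducibly from `seed` — switch to the rim's post-contrast T1,
#' emulating local accumulation of the albumin-binding agent where the
#' endothelium is leaky. All remaining voxels keep their pre-contrast T1.
#'
#' @param labels Compartment label volume from [rasterize_phantom()].
#' @param tissue A [tissue_params()].
#' @param protocol An [imaging_protocol()] with >= 2 flip angles.
#' @param ca_state `"pre"` or `"post"` contrast.
#' @param seed Integer seed (leak-voxel choice and noise).
#' @param noise_model Passed to [add_noise()].
#' @return A `vfa_series`; its `gt` field records the leaking voxel
#'   indices and the per-voxel true T1 volume.
#' @export
simulate_vfa_series <- function(labels, tissue, protocol = protocol_permeability(),
                                ca_state = c("pre", "post"), seed = 1L,
                                noise_model = "rician") {
  ca_state <- match.arg(ca_state)
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "imaging_protocol"))
  if (length(protocol$flip_angles_deg) < 2L)
    stop_ep("protocol must list at least 2 flip angles")
  if (tissue$noise_sigma < 0) stop_ep("'noise_sigma' must be >= 0")
  comp_of <- labels + 1L                     # codes 0..3 -> index 1..4
  comp_names <- c("background", "blood", "wall", "perivascular")
  t1 <- tissue$t1_pre_ms[comp_names][comp_of]
  m0 <- tissue$m0[comp_names][comp_of]
  dim(t1) <- dim(labels); dim(m0) <- dim(labels)
  leak_idx <- integer(0)
  with_seed(seed, {
    if (ca_state == "post") {
      t1[labels == COMPARTMENTS[["blood"]]] <- tissue$t1_post_ms[["blood"]]
      rim_idx <- which(labels == COMPARTMENTS[["perivascular"]])
      n_leak <- round(tissue$leak_fraction * length(rim_idx))
      if (n_leak > 0L) {
        leak_idx <- sort(sample(rim_idx, n_leak))
        t1[leak_idx] <- tissue$t1_post_ms[["perivascular"]]
      }
    }
    na <- length(protocol$flip_angles_deg)
    vol <- array(0, dim = c(dim(labels), na))
    for (a in seq_len(na)) {
      s <- spgr_signal(m0, t1, protocol$tr_ms, protocol$flip_angles_deg[a])
      vol[, , , a] <- add_noise(s, tissue$noise_sigma, noise_model)
    }
    new_vfa_series(vol, protocol$flip_angles_deg, protocol, ca_state,
                   gt = list(leak_idx = leak_idx, t1_true = t1))
  })
}

#' Paired pre/post-contrast permeability phantom
#'
#' Convenience wrapper building the full permeability experiment on a
#' straight-vessel phantom: rasterizes the geometry once, then simulates
#' the VFA series before and after contrast with a leak calibrated to an
#' exact number of rim voxels.
#'
#' @param n_leak Number of perivascular rim voxels that take up contrast
#'   (summed over the slice stack). Converted internally to the matching
#'   `leak_fraction`.
#' @param tissue A [tissue_params()]; its `leak_fraction` is overridden.
#' @param protocol Imaging protocol (default: the 8-angle permeability
#'   preset).
#' @param geometry Optional [vessel_geometry()]; default straight cylinder.
#' @param seed Integer seed.
#' @param rim_px Rim thickness in voxels.
#' @return List with `pre`/`post` `vfa_series`, the `labels` volume and
#'   the logical `rim_mask`.
#' @export
simulate_permeability_phantom <- function(n_leak, tissue = tissue_params(),
                                          protocol = protocol_permeability(),
                                          geometry = NULL, seed = 1L,
                                          rim_px = 2L) {
  if (is.null(geometry))
    geometry <- cylinder_geometry(protocol, radius_mm = 1.0,
                                  slant_mm_per_slice = c(0.061, 0.047),
                                  center_frac = c(0.47, 0.5))
  labels <- rasterize_phantom(geometry, protocol, frame = 0L, state = "pre",
                              rim_px = rim_px)
  rim_mask <- labels == COMPARTMENTS[["perivascular"]]
  n_rim <- sum(rim_mask)
  if (n_leak < 0 || n_leak > n_rim)
    stop_ep("'n_leak' must lie in [0, %d] (rim voxel count)", n_rim)
  tissue$leak_fraction <- n_leak / n_rim
  seeds <- derive_seeds(seed, 2L)
  pre <- simulate_vfa_series(labels, tissue, protocol, "pre", seeds[1])
  post <- simulate_vfa_series(labels, tissue, protocol, "post", seeds[2])
  list(pre = pre, post = post, labels = labels, rim_mask = rim_mask)
}
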