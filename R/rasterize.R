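# Compartment codes used throughout the phantom
COMPARTMENTS <- c(background = 0L, blood = 1L, wall = 2L, perivascular = 3L)

# Pulsation factor: raised cosine over the cardiac cycle, minimum (1.0,
# end-diastole) at the designated diastolic frame.
pulsation_factor <- function(amplitude, frame, diastolic_frame, n_frames) {
  if (n_frames <= 1L) return(1)
  1 + amplitude * (1 - cos(2 * pi * (frame - diastolic_frame) / n_frames)) / 2
}

# Cross-sections present on a given slice: list of (cx, cy, r) in mm after
# pulsation and (for state = "post") lumen dilation. radius scales with
# sqrt(dilation_factor) so that lumen volume scales with the factor itself.
slice_sections <- function(geometry, protocol, slice0, frame, state) {
  z <- (slice0) * protocol$voxel_mm[3]
  pf <- pulsation_factor(geometry$pulsation_amplitude, frame,
                         geometry$diastolic_frame, protocol$n_frames)
  df <- if (state == "post") sqrt(geometry$dilation_factor) else 1
  out <- list()
  cl <- geometry$centerline
  zr <- range(cl[, 3])
  if (z >= zr[1] - 1e-9 && z <= zr[2] + 1e-9) {
    out[[length(out) + 1L]] <- c(
      cx = stats::approx(cl[, 3], cl[, 1], z, rule = 2)$y,
      cy = stats::approx(cl[, 3], cl[, 2], z, rule = 2)$y,
      r  = stats::approx(cl[, 3], geometry$radius_mm, z, rule = 2)$y * pf * df)
  }
  bcl <- geometry$branch_centerline
  if (nrow(bcl) > 1L && z >= min(bcl[, 3]) - 1e-9 && z <= max(bcl[, 3]) + 1e-9) {
    out[[length(out) + 1L]] <- c(
      cx = stats::approx(bcl[, 3], bcl[, 1], z, rule = 2)$y,
      cy = stats::approx(bcl[, 3], bcl[, 2], z, rule = 2)$y,
      r  = stats::approx(bcl[, 3], geometry$branch_radius_mm, z, rule = 2)$y * pf * df)
  }
  out
}

# Partial-volume coverage fields for one slice. Returns matrices (nr x nc)
# with lumen / wall / rim coverage in [0, 1]; edges are anti-aliased with a
# one-pixel linear ramp emulating the point-spread function.
slice_coverage <- function(geometry, protocol, slice0, frame, state, rim_px = 2L) {
  nr <- protocol$matrix[1]; nc <- protocol$matrix[2]
  dx <- protocol$voxel_mm[1]; dy <- protocol$voxel_mm[2]
  w <- sqrt(dx * dy)                      # ramp width / rim voxel unit
  wt <- geometry$wall_thickness_mm
  rim_mm <- rim_px * w
  lum <- matrix(0, nr, nc); wal <- matrix(0, nr, nc); rim <- matrix(0, nr, nc)
  secs <- slice_sections(geometry, protocol, slice0, frame, state)
  for (s in secs) {
    rout <- s[["r"]] + wt + rim_mm + 2 * w
    if (s[["cx"]] - rout < 0 || s[["cx"]] + rout > protocol$fov_mm[1] ||
        s[["cy"]] - rout < 0 || s[["cy"]] + rout > protocol$fov_mm[2])
      stop_ep(paste0("vessel extent %.2f mm around (%.2f, %.2f) mm does not ",
                     "fit inside the %g x %g mm FOV at slice %d"),
              rout, s[["cx"]], s[["cy"]],
              protocol$fov_mm[1], protocol$fov_mm[2], slice0)
    i0 <- max(1L, floor((s[["cx"]] - rout) / dx)); i1 <- min(nr, ceiling((s[["cx"]] + rout) / dx) + 1L)
    j0 <- max(1L, floor((s[["cy"]] - rout) / dy)); j1 <- min(nc, ceiling((s[["cy"]] + rout) / dy) + 1L)
    xi <- ((i0:i1) - 0.5) * dx; yj <- ((j0:j1) - 0.5) * dy
    d <- sqrt(outer((xi - s[["cx"]])^2, (yj - s[["cy"]])^2, `+`))
    ramp <- function(radius) pmin(pmax(0.5 + (radius - d) / w, 0), 1)
    lum[i0:i1, j0:j1] <- pmax(lum[i0:i1, j0:j1], ramp(s[["r"]]))
    wal[i0:i1, j0:j1] <- pmax(wal[i0:i1, j0:j1], ramp(s[["r"]] + wt))
    rim[i0:i1, j0:j1] <- pmax(rim[i0:i1, j0:j1], ramp(s[["r"]] + wt + rim_mm))
  }
  list(lumen = lum, wall = pmax(wal - lum, 0), rim = pmax(rim - wal, 0))
}

#' Rasterize the vessel phantom to a compartment label volume
#'
#' Assigns every voxel of one cardiac frame to exactly one compartment:
#' background (0), blood/lumen (1), vessel wall (2) or perivascular rim (3).
#' A voxel is labelled by the compartment covering its centre (coverage
#' >= 0.5). The lumen radius is modulated by cardiac pulsation (minimum at
#' the geometry's diastolic frame) and, for `state = "post"`, scaled so the
#' lumen volume is multiplied by the geometry's `dilation_factor`.
#'
#' @param geometry A [vessel_geometry()].
#' @param protocol An [imaging_protocol()].
#' @param frame 0-based cardiac frame index (< `protocol$n_frames`).
#' @param state `"pre"` or `"post"` (acetylcholine); `"post"` applies the
#'   dilation factor.
#' @param rim_px Thickness of the perivascular rim, in voxels (default 2).
#' @return Integer array `matrix[1] x matrix[2] x matrix[3]` of compartment
#'   codes, with the code table attached as attribute `"compartments"`.
#' @examples
#' p <- imaging_protocol(10, 1.1, c(30, 30, 4), c(64, 64, 4), 30)
#' g <- default_geometry(p, branch_slice = 2L, slant_mm_per_slice = c(0, 0))
#' lab <- rasterize_phantom(g, p)
#' table(lab)
#' @export
rasterize_phantom <- function(geometry, protocol, frame = 0L,
                              state = c("pre", "post"), rim_px = 2L) {
  state <- match.arg(state)
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(protocol, "imaging_protocol"))
  if (frame < 0L || frame >= protocol$n_frames)
    stop_ep("'frame' must be a 0-based index below n_frames = %d", protocol$n_frames)
  nr <- protocol$matrix[1]; nc <- protocol$matrix[2]; nz <- protocol$matrix[3]
  lab <- array(COMPARTMENTS[["background"]], dim = c(nr, nc, nz))
  for (s in seq_len(nz)) {
    cov <- slice_coverage(geometry, protocol, s - 1L, frame, state, rim_px)
    sl <- matrix(COMPARTMENTS[["background"]], nr, nc)
    sl[cov$rim + cov$wall + cov$lumen >= 0.5] <- COMPARTMENTS[["perivascular"]]
    sl[cov$wall + cov$lumen >= 0.5] <- COMPARTMENTS[["wall"]]
    sl[cov$lumen >= 0.5] <- COMPARTMENTS[["blood"]]
    lab[, , s] <- sl
  }
  storage.mode(lab) <- "integer"
  attr(lab, "compartments") <- COMPARTMENTS
  attr(lab, "voxel_mm") <- protocol$voxel_mm
  lab
}
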