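#' Threshold segmentation of the vessel lumen on one slice
#'
#' Thresholds a single cross-sectional image, keeps the connected
#' component containing (or nearest to) the seed point, and fills holes.
#' The default threshold rule places the cutoff a fraction of the way
#' (default one half) between the background level (image median; the
#' background dominates the field of view) and the lumen intensity
#' estimated from a small window around the seed. Otsu's method is
#' available as an alternative.
#'
#' @param image_2d Numeric matrix (one slice, one frame); must not be
#'   constant.
#' @param pixel_mm Length-2 in-plane pixel size, mm.
#' @param seed_point Length-2, 0-based (row, col) of a point inside the
#'   lumen.
#' @param method `"fraction"` (fraction-of-range rule, default) or
#'   `"otsu"`.
#' @param fraction Threshold position between background and lumen levels,
#'   in (0, 1); default 0.5.
#' @return List with `mask` (logical matrix, single connected component,
#'   holes filled), `area_mm2` (= pixel count x pixel area), `threshold`,
#'   and `centroid` (0-based row/col of the component centroid).
#' @export
segment_lumen_slice <- function(image_2d, pixel_mm, seed_point,
                                method = c("fraction", "otsu"),
                                fraction = 0.5) {
  method <- match.arg(method)
  if (!is.matrix(image_2d)) stop_ep("'image_2d' must be a matrix")
  rng <- range(image_2d)
  if (diff(rng) == 0) stop_ep("image is constant; cannot threshold")
  nr <- nrow(image_2d); nc <- ncol(image_2d)
  sr <- round(seed_point[1]) + 1L; sc <- round(seed_point[2]) + 1L
  if (sr < 1L || sr > nr || sc < 1L || sc > nc)
    stop_ep("seed point (%d, %d) outside the image", seed_point[1], seed_point[2])
  if (method == "fraction") {
    bg <- stats::median(image_2d)
    win <- image_2d[max(1L, sr - 3L):min(nr, sr + 3L),
                    max(1L, sc - 3L):min(nc, sc + 3L)]
    peak <- stats::median(win)
    if (peak <= bg)
      stop_ep("seed window level (%.3g) not above background (%.3g); is the seed inside the lumen?",
              peak, bg)
    thr <- bg + fraction * (peak - bg)
  } else {
    norm <- (image_2d - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  }
  raw <- image_2d > thr
  if (!any(raw))
    stop_ep("empty mask at threshold %.4g (image range %.4g-%.4g)",
            thr, rng[1], rng[2])
  lab <- EBImage::bwlabel(EBImage::Image(raw * 1))
  lab <- EBImage::imageData(lab)
  id <- lab[sr, sc]
  if (id == 0) {                       # nearest component to the seed
    on <- which(lab > 0, arr.ind = TRUE)
    d2 <- (on[, 1] - sr)^2 + (on[, 2] - sc)^2
    id <- lab[on[which.min(d2), , drop = FALSE]]
  }
  mask <- lab == id
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  on <- which(mask, arr.ind = TRUE)
  list(mask = mask,
       area_mm2 = sum(mask) * pixel_mm[1] * pixel_mm[2],
       threshold = thr,
       centroid = c(mean(on[, 1]), mean(on[, 2])) - 1)
}

# Segment a set of slices of one frame, tracking the lumen centroid from
# slice to slice so the seed follows a slanted vessel. `slices` is 0-based.
track_segment_stack <- function(vol3d, slices, pixel_mm, seed_point,
                                method = "fraction", fraction = 0.5) {
  masks <- vector("list", length(slices))
  areas <- rep(NA_real_, length(slices))
  seed <- seed_point
  for (k in seq_along(slices)) {
    seg <- segment_lumen_slice(vol3d[, , slices[k] + 1L], pixel_mm, seed,
                               method, fraction)
    masks[[k]] <- seg$mask; areas[k] <- seg$area_mm2
    seed <- seg$centroid
  }
  list(masks = masks, areas = areas, slices = slices)
}

#' Select the end-diastolic cardiac frame
#'
#' Identifies diastole as the frame minimizing the total segmented lumen
#' area over a set of slices. Ties break to the lowest frame index; a
#' single-frame cine returns frame 0.
#'
#' @param cine A `cine_volume`.
#' @param seed_point 0-based (row, col) inside the lumen.
#' @param slices 0-based slice indices to sum over (default: the first 8
#'   slices, i.e. the proximal vessel).
#' @param method,fraction Passed to [segment_lumen_slice()].
#' @return 0-based frame index.
#' @export
select_diastolic_frame <- function(cine, seed_point, slices = NULL,
                                   method = "fraction", fraction = 0.5) {
  stopifnot(inherits(cine, "cine_volume"))
  nf <- dim(cine$intensities)[4]
  if (nf == 1L) return(0L)
  nz <- dim(cine$intensities)[3]
  if (is.null(slices)) slices <- 0:(min(8L, nz) - 1L)
  px <- cine$voxel_mm[1:2]
  totals <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    tot <- 0; nok <- 0L
    seed <- seed_point
    for (s in slices) {
      seg <- tryCatch(segment_lumen_slice(cine$intensities[, , s + 1L, f],
                                          px, seed, method, fraction),
                      error = function(e) NULL)
      if (!is.null(seg)) { tot <- tot + seg$area_mm2; nok <- nok + 1L; seed <- seg$centroid }
    }
    if (nok > 0L) totals[f] <- tot
  }
  if (all(is.na(totals)))
    stop_ep("lumen segmentation failed on every frame")
  which.min(totals) - 1L
}

#' Select the contiguous analysis slices proximal to the branch
#'
#' Returns the block of `n_slices` contiguous slices ending strictly
#' before the first slice on which the thresholded lumen splits into two
#' connected components (the bifurcation). An explicit 0-based override
#' range is returned verbatim.
#'
#' @param cine A `cine_volume`.
#' @param seed_point 0-based (row, col) inside the lumen on the first
#'   slice.
#' @param frame 0-based frame to analyse (default: 0).
#' @param n_slices Number of slices requested (default 5).
#' @param override Optional 0-based vector of slice indices, returned
#'   verbatim after bounds checking.
#' @param min_component_px Minimum size for a component to count as a
#'   lumen cross-section.
#' @param method,fraction Passed to the threshold rule.
#' @return 0-based vector of `n_slices` contiguous slice indices.
#' @export
select_analysis_slices <- function(cine, seed_point, frame = 0L, n_slices = 5L,
                                   override = NULL, min_component_px = 9L,
                                   method = "fraction", fraction = 0.5) {
  stopifnot(inherits(cine, "cine_volume"))
  nz <- dim(cine$intensities)[3]
  if (!is.null(override)) {
    if (any(override < 0L) || any(override >= nz))
      stop_ep("override slices outside 0..%d", nz - 1L)
    return(as.integer(override))
  }
  if (n_slices > nz) stop_ep("requested %d slices but only %d available", n_slices, nz)
  px <- cine$voxel_mm[1:2]
  seed <- seed_point
  branch <- NA_integer_
  for (s in 0:(nz - 1L)) {
    img <- cine$intensities[, , s + 1L, frame + 1L]
    seg <- tryCatch(segment_lumen_slice(img, px, seed, method, fraction),
                    error = function(e) NULL)
    if (is.null(seg)) next
    seed <- seg$centroid
    # count lumen-sized components in the full thresholded mask
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((img > seg$threshold) * 1)))
    sizes <- tabulate(lab[lab > 0])
    if (sum(sizes >= min_component_px) >= 2L) { branch <- s; break }
  }
  if (is.na(branch))
    stop_ep("no branch (slice with two lumen components) found and no override given")
  if (branch < n_slices)
    stop_ep("branch at slice %d leaves fewer than %d proximal slices", branch, n_slices)
  (branch - n_slices):(branch - 1L)
}

#' Reconstruct a lumen volume from slice-wise areas
#'
#' Rectangular-rule volume: the sum of cross-sectional areas times the
#' slice thickness.
#'
#' @param areas_mm2 Numeric vector of per-slice lumen areas (mm^2), or the
#'   list returned by [track_segment_stack()]-style segmentation with an
#'   `areas` field.
#' @param slice_thickness_mm Slice thickness, mm.
#' @return Volume in mm^3.
#' @examples
#' reconstruct_volume(2, 0.167)
#' @export
reconstruct_volume <- function(areas_mm2, slice_thickness_mm) {
  if (is.list(areas_mm2)) areas_mm2 <- areas_mm2$areas
  if (length(areas_mm2) < 1L) stop_ep("at least one slice area is required")
  if (any(!is.finite(areas_mm2)) || any(areas_mm2 < 0))
    stop_ep("areas must be finite and >= 0")
  check_scalar_pos(slice_thickness_mm, "slice_thickness_mm")
  sum(areas_mm2) * slice_thickness_mm
}

#' Percent change of end-diastolic volume
#'
#' `100 * (v_post - v_pre) / v_pre`; negative = vasoconstriction,
#' positive = vasodilatation.
#'
#' @param v_pre,v_post Volumes (same units), `v_pre > 0`.
#' @return Percent change.
#' @examples
#' volume_change_percent(1.0, 0.9282)  # -7.18
#' @export
volume_change_percent <- function(v_pre, v_post) {
  if (any(v_pre <= 0)) stop_ep("'v_pre' must be > 0")
  100 * (v_post - v_pre) / v_pre
}

#' End-to-end vasomotor response measurement
#'
#' Full analysis of a pre/post-acetylcholine cine pair: selects the
#' end-diastolic frame on each cine, determines the analysis slices
#' (5 contiguous slices ending just before the branch) on the pre scan,
#' segments the lumen slice-wise on both scans with centroid tracking,
#' reconstructs the two end-diastolic volumes and reports the percent
#' change.
#'
#' @param pre,post `cine_volume`s of the two vasomotor states.
#' @param seed_point 0-based (row, col) inside the lumen on the proximal
#'   slices.
#' @param n_slices Number of analysis slices (default 5).
#' @param slices Optional 0-based override for the analysis slices.
#' @param method,fraction Threshold rule (see [segment_lumen_slice()]).
#' @return Object of class `vasomotion_result`.
#' @export
measure_vasomotion <- function(pre, post, seed_point, n_slices = 5L,
                               slices = NULL, method = "fraction",
                               fraction = 0.5) {
  stopifnot(inherits(pre, "cine_volume"), inherits(post, "cine_volume"))
  f_pre <- select_diastolic_frame(pre, seed_point, method = method, fraction = fraction)
  f_post <- select_diastolic_frame(post, seed_point, method = method, fraction = fraction)
  sl <- select_analysis_slices(pre, seed_point, frame = f_pre,
                               n_slices = n_slices, override = slices,
                               method = method, fraction = fraction)
  px <- pre$voxel_mm[1:2]
  seg_pre <- track_segment_stack(pre$intensities[, , , f_pre + 1L], sl, px,
                                 seed_point, method, fraction)
  seg_post <- track_segment_stack(post$intensities[, , , f_post + 1L], sl, px, seed_point, method, fraction)
  v_pre <- reconstruct_volume(seg_pre$areas, pre$voxel_mm[3])
  v_post <- reconstruct_volume(seg_post$areas, post$voxel_mm[3])
  structure(list(v_pre_mm3 = v_pre, v_post_mm3 = v_post,
                 percent_change = volume_change_percent(v_pre, v_post),
                 diastolic_frame_pre = f_pre, diastolic_frame_post = f_post,
                 slices = sl,
                 areas_pre_mm2 = seg_pre$areas, areas_post_mm2 = seg_post$areas),
            class = "vasomotion_result")
}

#' @export
print.vasomotion_result <- function(x, ...) {
  cat("<vasomotion_result>\n")
  cat(sprintf("  end-diastolic BCA volume: pre %.4f mm^3, post %.4f mm^3\n",
              x$v_pre_mm3, x$v_post_mm3))
  cat(sprintf("  response: %+.2f%% (%s)\n", x$percent_change,
              if (x$percent_change < 0) "vasoconstriction" else "vasodilatation"))
  cat(sprintf("  diastolic frame %d (pre) / %d (post); slices %s\n",
              x$diastolic_frame_pre, x$diastolic_frame_post,
              paste(range(x$slices), collapse = "-")))
  invisible(x)
}
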