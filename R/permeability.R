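as_t1_array <- function(x) {
  if (inherits(x, "t1_map")) x$t1_ms else x
}

#' Perivascular analysis region around a lumen
#'
#' Builds the ring of pixels analysed for contrast leakage: the
#' morphological dilation of the lumen mask by `rim_thickness_px` minus the
#' lumen itself, so the region is always disjoint from the lumen. 3D masks
#' are processed slice-wise (in-plane rim).
#'
#' @param lumen_mask Logical matrix or 3D array (TRUE = lumen).
#' @param rim_thickness_px Integer rim thickness in pixels (>= 1).
#' @param connectivity 4 (city-block / diamond structuring element) or
#'   8 (chessboard / box).
#' @return Logical mask of the same shape.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' sum(perivascular_roi(m, 1))  # the 4 edge neighbours
#' @export
perivascular_roi <- function(lumen_mask, rim_thickness_px, connectivity = 4) {
  if (rim_thickness_px < 1 || rim_thickness_px != round(rim_thickness_px))
    stop_ep("'rim_thickness_px' must be an integer >= 1")
  if (!any(lumen_mask)) stop_ep("'lumen_mask' is empty")
  if (!connectivity %in% c(4, 8)) stop_ep("'connectivity' must be 4 or 8")
  shape <- if (connectivity == 4) "diamond" else "box"
  brush <- EBImage::makeBrush(2L * rim_thickness_px + 1L, shape = shape)
  dil2d <- function(m) {
    d <- EBImage::dilate(EBImage::Image(m * 1), brush)
    EBImage::imageData(d) > 0.5
  }
  if (length(dim(lumen_mask)) == 2L) {
    out <- dil2d(lumen_mask) & !lumen_mask
  } else {
    out <- array(FALSE, dim = dim(lumen_mask))
    for (s in seq_len(dim(lumen_mask)[3]))
      out[, , s] <- dil2d(lumen_mask[, , s]) & !lumen_mask[, , s]
  }
  out
}

#' Relative T1 change between pre- and post-contrast maps
#'
#' Per-pixel relative change `(t1_pre - t1_post) / t1_pre` (a positive
#' value is a T1 *decrease*, the direction the gadolinium agent produces).
#' With `direction = "absolute"` the magnitude of the change is returned
#' instead. Pixels undefined in either map are `NA`.
#'
#' @param t1_pre,t1_post `t1_map` objects or numeric arrays of equal shape.
#' @param direction `"decrease"` (default) or `"absolute"`.
#' @return Numeric array of relative changes.
#' @export
relative_t1_change <- function(t1_pre, t1_post,
                               direction = c("decrease", "absolute")) {
  direction <- match.arg(direction)
  pre <- as_t1_array(t1_pre); post <- as_t1_array(t1_post)
  if (!identical(dim(pre), dim(post)))
    stop_ep("T1 maps have different shapes (%s vs %s)",
            paste(dim(pre), collapse = "x"), paste(dim(post), collapse = "x"))
  ch <- (pre - post) / pre
  if (direction == "absolute") ch <- abs(ch)
  ch
}

#' Npx50: count of pixels whose T1 changed by more than the threshold
#'
#' The permeability endpoint: within the perivascular analysis region,
#' counts the pixels whose relative T1 change after contrast-agent
#' administration *strictly* exceeds the threshold (default 0.50, i.e.
#' "changed by more than 50\%"). Pixels with a failed T1 fit in either map
#' are excluded from both the region size and the count; their number is
#' reported.
#'
#' @param t1_pre,t1_post Pre/post-contrast `t1_map`s or arrays.
#' @param roi_mask Logical mask of the analysis region (non-empty).
#' @param threshold Relative-change cutoff in (0, 1); default 0.50.
#' @param direction Counted change: `"decrease"` (default; the agent
#'   shortens T1) or `"absolute"`.
#' @return Object of class `permeability_result`: `npx50`, `changed_mask`,
#'   `roi_mask`, `roi_size` (evaluable pixels), `excluded`, `threshold`,
#'   `direction`.
#' @examples
#' pre <- matrix(1200, 4, 4); post <- matrix(1200, 4, 4); post[1, 1] <- 500
#' roi <- matrix(TRUE, 4, 4)
#' compute_npx50(pre, post, roi)$npx50
#' @export
compute_npx50 <- function(t1_pre, t1_post, roi_mask, threshold = 0.5,
                          direction = c("decrease", "absolute")) {
  direction <- match.arg(direction)
  if (threshold <= 0 || threshold >= 1) stop_ep("'threshold' must lie in (0, 1)")
  pre <- as_t1_array(t1_pre); post <- as_t1_array(t1_post)
  if (!any(roi_mask)) stop_ep("ROI mask is empty")
  ch <- relative_t1_change(pre, post, direction)
  evaluable <- roi_mask & !is.na(ch)
  if (!any(evaluable))
    stop_ep("no evaluable pixels: every ROI pixel is undefined in a T1 map")
  changed <- evaluable & !is.na(ch) & ch > threshold
  structure(list(npx50 = sum(changed), changed_mask = changed,
                 roi_mask = roi_mask, roi_size = sum(evaluable),
                 excluded = sum(roi_mask) - sum(evaluable),
                 threshold = threshold, direction = direction),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> Npx50 = %d of %d evaluable ROI pixels (threshold %.2f, %s)\n",
              x$npx50, x$roi_size, x$threshold, x$direction))
  if (x$excluded > 0)
    cat(sprintf("  %d ROI pixel(s) excluded (undefined T1 fit)\n", x$excluded))
  invisible(x)
}

#' Overlay of changed pixels on a T1 map slice
#'
#' Renders one slice of the pre-contrast T1 map in grey with the
#' changed (Npx50-counted) pixels marked in red.
#'
#' @param x A `permeability_result`.
#' @param t1_pre Pre-contrast `t1_map` or array used for the background.
#' @param slice 0-based slice index (for 3D data).
#' @param ... Ignored.
#' @export
plot.permeability_result <- function(x, t1_pre, slice = 0L, ...) {
  bg <- as_t1_array(t1_pre)
  ch <- x$changed_mask
  if (length(dim(bg)) == 3L) { bg <- bg[, , slice + 1L]; ch <- ch[, , slice + 1L] }
  bg[is.na(bg)] <- 0
  graphics::image(bg, col = grey.colors(128), axes = FALSE, asp = 1,
                  main = sprintf("Npx50 = %d", x$npx50))
  red <- matrix(NA_real_, nrow(ch), ncol(ch)); red[ch] <- 1
  graphics::image(red, col = "red", add = TRUE)
  invisible(x)
}
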