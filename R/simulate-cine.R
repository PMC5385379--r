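#' Add magnitude (Rician) noise to a noiseless signal
#'
#' Magnitude MRI noise: the noiseless signal is perturbed by independent
#' Gaussian noise in both quadrature channels and the modulus taken,
#' `sqrt((x + n1)^2 + n2^2)`. Where the true signal is zero this yields a
#' Rayleigh-distributed background. A plain additive Gaussian model is
#' available for debugging.
#'
#' @param x Numeric array of noiseless magnitudes.
#' @param sigma Noise scale (>= 0), signal units.
#' @param model `"rician"` (default) or `"gaussian"`.
#' @return Array of the same shape; all values >= 0 under the Rician model.
#' @export
add_noise <- function(x, sigma, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (sigma < 0) stop_ep("'sigma' must be >= 0")
  if (sigma == 0) return(x)
  n <- length(x)
  if (model == "rician") {
    out <- sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  } else {
    out <- x + stats::rnorm(n, 0, sigma)
  }
  dim(out) <- dim(x)
  out
}

new_cine_volume <- function(intensities, protocol, state, gt = list()) {
  structure(list(intensities = intensities, protocol = protocol,
                 voxel_mm = protocol$voxel_mm, state = state, gt = gt),
            class = "cine_volume")
}

#' @export
print.cine_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<cine_volume> %s: %d x %d x %d voxels, %d frame(s), voxel %s mm\n",
              x$state, d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_mm, 4), collapse = " x ")))
  invisible(x)
}

#' Simulate pre/post-acetylcholine cine volumes
#'
#' Generates the pair of 4D cine magnitude stacks the vasomotion analysis
#' consumes: one per vasomotor state, sharing geometry except that the
#' post-acetylcholine lumen volume is multiplied by the geometry's
#' `dilation_factor`. Intensities are a partial-volume mixture of the
#' per-compartment cine intensities (bright blood, darker wall, dark
#' background), and Rician noise of scale `tissue$noise_sigma` is applied
#' independently per voxel and frame.
#'
#' @param geometry A [vessel_geometry()].
#' @param tissue A [tissue_params()]; `cine_intensity` and `noise_sigma`
#'   are used.
#' @param protocol An [imaging_protocol()] with `n_frames >= 1`.
#' @param seed Integer seed; the pair is bit-reproducible given
#'   (inputs, seed).
#' @param noise_model Passed to [add_noise()].
#' @return List with elements `pre` and `post`, each a `cine_volume` whose
#'   `gt` field records the ground-truth diastolic frame, branch slice (if
#'   known) and analytic end-diastolic lumen volumes.
#' @export
simulate_cine <- function(geometry, tissue, protocol = protocol_function(),
                          seed = 1L, noise_model = "rician") {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(tissue, "tissue_params"),
            inherits(protocol, "imaging_protocol"))
  int <- tissue$cine_intensity
  nr <- protocol$matrix[1]; nc <- protocol$matrix[2]; nz <- protocol$matrix[3]
  nf <- protocol$n_frames
  render <- function(state) {
    vol <- array(int[["background"]], dim = c(nr, nc, nz, nf))
    for (f in seq_len(nf) - 1L) for (s in seq_len(nz) - 1L) {
      cov <- slice_coverage(geometry, protocol, s, f, state)
      sl <- int[["background"]] +
        (int[["blood"]] - int[["background"]]) * cov$lumen +
        (int[["wall"]] - int[["background"]]) * cov$wall +
        (int[["perivascular"]] - int[["background"]]) * cov$rim
      vol[, , s + 1L, f + 1L] <- sl
    }
    vol
  }
  lumen_mm3 <- function(state) {
    df <- if (state == "post") geometry$dilation_factor else 1
    a <- 0
    for (s in seq_len(nz) - 1L) {
      secs <- slice_sections(geometry, protocol, s, geometry$diastolic_frame, state)
      a <- a + sum(vapply(secs, function(x) pi * x[["r"]]^2, 0))
    }
    a * protocol$voxel_mm[3]
  }
  gt <- list(diastolic_frame = geometry$diastolic_frame,
             branch_slice = attr(geometry, "branch_slice") %||% NA_integer_,
             dilation_factor = geometry$dilation_factor,
             lumen_mm3_pre = lumen_mm3("pre"),
             lumen_mm3_post = lumen_mm3("post"))
  with_seed(seed, {
    pre <- add_noise(render("pre"), tissue$noise_sigma, noise_model)
    post <- add_noise(render("post"), tissue$noise_sigma, noise_model)
    list(pre = new_cine_volume(pre, protocol, "pre", gt),
         post = new_cine_volume(post, protocol, "post", gt))
  })
}
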