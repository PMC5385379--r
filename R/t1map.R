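#' Spoiled gradient-echo steady-state signal
#'
#' The ideal spoiled gradient-echo (FLASH) magnitude at steady state,
#' `S = m0 * sin(a) * (1 - E) / (1 - E * cos(a))` with
#' `E = exp(-TR / T1)`. This is both the forward model of the phantom
#' generator and the model fitted per pixel by the variable flip angle
#' (VFA) method.
#'
#' @param m0 Equilibrium signal (arbitrary units, >= 0).
#' @param t1_ms Longitudinal relaxation time, ms (> 0).
#' @param tr_ms Repetition time, ms (> 0).
#' @param alpha_deg Flip angle in degrees, in [0, 90].
#' @return Signal magnitude (>= 0); 0 when `alpha_deg = 0` or `m0 = 0`.
#'   Vectorized over all arguments.
#' @examples
#' spgr_signal(100, 1000, 10, 14)
#' @export
spgr_signal <- function(m0, t1_ms, tr_ms, alpha_deg) {
  if (any(t1_ms <= 0)) stop_ep("'t1_ms' must be > 0")
  if (any(tr_ms <= 0)) stop_ep("'tr_ms' must be > 0")
  if (any(alpha_deg < 0 | alpha_deg > 90))
    stop_ep("'alpha_deg' must lie in [0, 90]")
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

# Core VFA fit on a signal matrix (pixels x angles). Returns per-pixel
# t1, m0, r2, reason (0 ok / 1 no signal / 2 non-physical estimate).
# Linear step: DESPOT1-style linearization S/sin = E * S/tan + m0(1-E);
# nonlinear step: vectorized Levenberg-Marquardt on (m0, T1) started from
# the linear estimate, reverting to it if refinement does not reduce SSE.
fit_t1_core <- function(S, flip_angles_deg, tr_ms, method = "nonlinear",
                        t1_max = 10000, max_iter = 30L) {
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
  na <- length(flip_angles_deg)
  if (ncol(S) != na)
    stop_ep("number of signals (%d) does not match number of flip angles (%d)",
            ncol(S), na)
  if (na < 2L) stop_ep("at least 2 flip angles are required")
  if (length(unique(flip_angles_deg)) < 2L)
    stop_ep("degenerate design: all flip angles are equal")
  a <- flip_angles_deg * pi / 180
  sa <- sin(a); ta <- tan(a); ca <- cos(a)
  np <- nrow(S)
  reason <- integer(np)
  t1 <- rep(NA_real_, np); m0 <- rep(NA_real_, np)

  nosig <- rowSums(abs(S)) == 0 | !is.finite(rowSums(S))
  reason[nosig] <- 1L

  y <- sweep(S, 2L, sa, `/`)
  x <- sweep(S, 2L, ta, `/`)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  denom <- na * sxx - sx^2
  E <- (na * sxy - sx * sy) / denom
  m0l <- (sy / na - E * sx / na) / (1 - E)
  ok <- !nosig & is.finite(E) & E > 0 & E < 1 & is.finite(m0l) & m0l > 0
  t1l <- rep(NA_real_, np)
  t1l[ok] <- -tr_ms / log(E[ok])
  ok <- ok & !is.na(t1l) & t1l > 0 & t1l <= t1_max
  reason[!ok & !nosig] <- 2L

  t1[ok] <- t1l[ok]; m0[ok] <- m0l[ok]

  sse_of <- function(m0v, t1v, idx) {
    e1 <- exp(-tr_ms / t1v)
    f <- outer(m0v, sa) * (1 - e1) / (1 - outer(e1, ca))
    rowSums((S[idx, , drop = FALSE] - f)^2)
  }

  if (method == "nonlinear" && any(ok)) {
    idx <- which(ok)
    p_m0 <- m0[idx]; p_t1 <- t1[idx]
    sse <- sse_of(p_m0, p_t1, idx)
    sse_lin <- sse
    lambda <- rep(1e-3, length(idx))
    for (it in seq_len(max_iter)) {
      e1 <- exp(-tr_ms / p_t1)
      Ef <- outer(e1, ca)
      f <- outer(p_m0, sa) * (1 - e1) / (1 - Ef)
      r <- S[idx, , drop = FALSE] - f
      J1 <- sweep(f, 1L, p_m0, `/`)                       # df/dm0
      dfdE <- outer(p_m0, sa) * (rep(1, length(idx)) %o% (ca - 1)) / (1 - Ef)^2
      J2 <- dfdE * (e1 * tr_ms / p_t1^2)                  # df/dT1
      A11 <- rowSums(J1 * J1); A12 <- rowSums(J1 * J2); A22 <- rowSums(J2 * J2)
      b1 <- rowSums(J1 * r); b2 <- rowSums(J2 * r)
      d11 <- A11 * (1 + lambda); d22 <- A22 * (1 + lambda)
      det <- d11 * d22 - A12^2
      det[abs(det) < 1e-300] <- NA
      dm0 <- (d22 * b1 - A12 * b2) / det
      dt1 <- (d11 * b2 - A12 * b1) / det
      new_m0 <- pmax(p_m0 + ifelse(is.na(dm0), 0, dm0), 1e-12)
      new_t1 <- pmin(pmax(p_t1 + ifelse(is.na(dt1), 0, dt1), 1e-3), 2 * t1_max)
      new_sse <- sse_of(new_m0, new_t1, idx)
      better <- is.finite(new_sse) & new_sse <= sse
      p_m0[better] <- new_m0[better]; p_t1[better] <- new_t1[better]
      sse[better] <- new_sse[better]
      lambda <- ifelse(better, pmax(lambda / 3, 1e-12), pmin(lambda * 10, 1e8))
      if (all(abs(c(dm0, dt1)) < 1e-10, na.rm = TRUE)) break
    }
    # keep refinement only where it did not worsen the fit
    keep <- sse <= sse_lin & p_t1 > 0 & p_t1 <= t1_max
    m0[idx[keep]] <- p_m0[keep]; t1[idx[keep]] <- p_t1[keep]
    bad <- p_t1 > t1_max & t1l[idx] > t1_max
    if (any(bad)) { t1[idx[bad]] <- NA; m0[idx[bad]] <- NA; reason[idx[bad]] <- 2L }
  }

  r2 <- rep(NA_real_, np)
  good <- !is.na(t1)
  if (any(good)) {
    idx <- which(good)
    sse <- sse_of(m0[idx], t1[idx], idx)
    sbar <- rowMeans(S[idx, , drop = FALSE])
    sst <- rowSums(sweep(S[idx, , drop = FALSE], 1L, sbar)^2)
    r2[idx] <- ifelse(sst > 0, pmin(pmax(1 - sse / sst, 0), 1),
                      as.numeric(sse <= 1e-24))
  }
  list(t1_ms = t1, m0 = m0, fit_quality = r2, reason = reason)
}

#' Fit the VFA model for a single pixel
#'
#' Estimates (T1, M0) from magnitudes acquired at several flip angles.
#' The linear method solves the linearization
#' `S/sin(a) = E * S/tan(a) + m0 * (1 - E)` by least squares and maps the
#' slope to T1; the nonlinear method refines that estimate by minimizing
#' the squared residuals of [spgr_signal()]. Estimates outside
#' `(0, t1_max]`, non-physical slopes (`E <= 0` or `E >= 1`) and all-zero
#' signal vectors yield an undefined result with a coded reason rather
#' than a clamped value.
#'
#' @param signals Magnitudes, one per flip angle.
#' @param flip_angles_deg Flip angles, degrees.
#' @param tr_ms Repetition time, ms.
#' @param method `"nonlinear"` (default) or `"linear"`.
#' @param t1_max Upper bound for admissible T1 estimates, ms.
#' @return List with `t1_ms`, `m0`, `fit_quality` (coefficient of
#'   determination), `ok`, and `reason`
#'   (`"ok"`, `"no_signal"` or `"non_physical"`).
#' @examples
#' s <- spgr_signal(100, 800, 10, c(2, 4, 6, 8, 14, 20, 30, 50))
#' fit_t1_pixel(s, c(2, 4, 6, 8, 14, 20, 30, 50), 10)$t1_ms
#' @export
fit_t1_pixel <- function(signals, flip_angles_deg, tr_ms,
                         method = c("nonlinear", "linear"), t1_max = 10000) {
  method <- match.arg(method)
  if (length(signals) != length(flip_angles_deg))
    stop_ep("number of signals (%d) does not match number of flip angles (%d)",
            length(signals), length(flip_angles_deg))
  fit <- fit_t1_core(matrix(signals, nrow = 1L), flip_angles_deg, tr_ms,
                     method, t1_max)
  list(t1_ms = fit$t1_ms[1], m0 = fit$m0[1], fit_quality = fit$fit_quality[1],
       ok = fit$reason[1] == 0L,
       reason = c("ok", "no_signal", "non_physical")[fit$reason[1] + 1L])
}

#' Pixel-by-pixel T1 map from a variable flip angle series
#'
#' Applies the VFA fit under a mask and assembles T1, M0 and fit-quality
#' maps. Failed pixels (no signal, non-physical slope, T1 out of range)
#' are `NA` in all maps and carry a reason code; they propagate as missing
#' values, never as zeros, so that downstream change statistics cannot
#' mistake a failed fit for a total T1 change.
#'
#' @param series A `vfa_series` (see [simulate_vfa_series()] /
#'   [read_vfa_series()]).
#' @param mask Logical array matching one volume; pixels to fit. Default:
#'   all pixels.
#' @param method,t1_max Passed to the fit (see [fit_t1_pixel()]).
#' @return Object of class `t1_map` with fields `t1_ms`, `m0`,
#'   `fit_quality`, `mask`, `reason` (integer codes), `failed_fraction`.
#' @export
fit_t1_map <- function(series, mask = NULL, method = c("nonlinear", "linear"),
                       t1_max = 10000) {
  method <- match.arg(method)
  stopifnot(inherits(series, "vfa_series"))
  dims <- dim(series$volumes)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (!identical(dim(mask), as.integer(dims)) &&
      !identical(dim(mask), dims))
    stop_ep("mask shape does not match the series volumes")
  if (!any(mask)) stop_ep("empty mask: no pixels to fit")
  na <- length(series$flip_angles_deg)
  idx <- which(mask)
  S <- matrix(0, length(idx), na)
  nvox <- prod(dims)
  for (a in seq_len(na)) S[, a] <- series$volumes[idx + (a - 1L) * nvox]
  fit <- fit_t1_core(S, series$flip_angles_deg, series$protocol$tr_ms,
                     method, t1_max)
  shape <- function(v, fill = NA_real_) {
    out <- array(fill, dim = dims); out[idx] <- v; out
  }
  structure(list(
    t1_ms = shape(fit$t1_ms), m0 = shape(fit$m0),
    fit_quality = shape(fit$fit_quality),
    mask = mask, reason = shape(fit$reason, NA_integer_),
    failed_fraction = mean(fit$reason != 0L),
    method = method, t1_max = t1_max,
    tr_ms = series$protocol$tr_ms,
    flip_angles_deg = series$flip_angles_deg,
    voxel_mm = series$protocol$voxel_mm
  ), class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  d <- dim(x$t1_ms)
  cat(sprintf("<t1_map> %s fit, %s voxels, TR %.2f ms, %d angles\n",
              x$method, paste(d, collapse = " x "), x$tr_ms,
              length(x$flip_angles_deg)))
  cat(sprintf("  fitted %d pixels, %.1f%% failed\n",
              sum(x$mask), 100 * x$failed_fraction))
  q <- stats::quantile(x$t1_ms[x$mask], c(0.05, 0.5, 0.95), na.rm = TRUE)
  cat(sprintf("  T1 (ms): 5%% %.0f, median %.0f, 95%% %.0f\n", q[1], q[2], q[3]))
  invisible(x)
}

#' @export
summary.t1_map <- function(object, ...) {
  v <- object$t1_ms[object$mask]
  out <- list(n = sum(object$mask), n_failed = sum(is.na(v)),
              failed_fraction = object$failed_fraction,
              t1_summary = summary(v),
              r2_summary = summary(object$fit_quality[object$mask]))
  class(out) <- "summary.t1_map"
  out
}

#' @export
print.summary.t1_map <- function(x, ...) {
  cat(sprintf("T1 map: %d pixels fitted, %d failed (%.1f%%)\n",
              x$n, x$n_failed, 100 * x$failed_fraction))
  cat("T1 (ms):\n"); print(x$t1_summary)
  cat("fit quality (R^2):\n"); print(x$r2_summary)
  invisible(x)
}
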