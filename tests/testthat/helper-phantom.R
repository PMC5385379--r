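# Shared small-scale fixtures, generated in code.

paper_angles <- c(2, 4, 6, 8, 14, 20, 30, 50)

# small cine protocol: 96x96 in-plane over a 12 mm FOV (0.125 mm pixels)
small_cine_protocol <- function(nz = 10L, n_frames = 3L) {
  imaging_protocol(6.4, 1.4, c(12, 12, nz * 1 / 6), c(96, 96, nz), 30,
                   n_frames = n_frames, label = "test cine")
}

# small VFA protocol with the 8 study angles
small_vfa_protocol <- function(nz = 2L, nxy = 48L) {
  imaging_protocol(10, 1.1, c(12, 12, nz * 0.5), c(nxy, nxy, nz),
                   paper_angles, n_frames = 1L, label = "test VFA")
}

small_cylinder <- function(protocol, radius_mm = 1.0, ...) {
  cylinder_geometry(protocol, radius_mm = radius_mm,
                    center_frac = c(0.52, 0.49), ...)
}

noiseless_tissue <- function(...) {
  t <- tissue_params(...)
  t$noise_sigma <- 0
  t
}

# VFA noise scale giving the requested SNR at the largest flip angle for
# the given (m0, T1, TR)
vfa_sigma_for_snr <- function(snr, m0 = 100, t1_ms = 1000, tr_ms = 10,
                              max_angle = 50) {
  spgr_signal(m0, t1_ms, tr_ms, max_angle) / snr
}

# independent Bloch-iteration oracle for the spoiled gradient-echo steady
# state: rotate by alpha (perfect spoiling of transverse magnetization),
# relax over TR, repeat to convergence
bloch_spgr_oracle <- function(m0, t1_ms, tr_ms, alpha_deg, tol = 1e-14) {
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  mz <- m0
  repeat {
    mz_new <- m0 + (mz * cos(a) - m0) * e1
    if (abs(mz_new - mz) < tol * m0) break
    mz <- mz_new
  }
  mz * sin(a)
}

# brute-force tie-corrected Kruskal-Wallis H
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(ns * rbar^2) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
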