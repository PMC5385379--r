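test_that("SPGR signal obeys its limits and the Bloch-iteration oracle", {
  expect_equal(spgr_signal(100, 1000, 10, 0), 0)
  expect_equal(spgr_signal(0, 1000, 10, 30), 0)
  # saturation-recovery limit TR >> T1: S -> m0 sin(alpha)
  expect_equal(spgr_signal(100, 10, 1e6, 30), 50, tolerance = 1e-10)
  # iterative Bloch steady state with perfect spoiling
  for (alpha in c(5, 14, 30, 50)) {
    expect_equal(spgr_signal(1000, 1000, 10, alpha),
                 bloch_spgr_oracle(1000, 1000, 10, alpha),
                 tolerance = 1e-10)
  }
  expect_error(spgr_signal(100, -5, 10, 30), "t1_ms")
  expect_error(spgr_signal(100, 1000, 0, 30), "tr_ms")
})

test_that("noiseless VFA fit inverts the forward model exactly", {
  for (t1 in c(200, 500, 1000, 2000, 4000)) {
    s <- spgr_signal(100, t1, 10, paper_angles)
    for (m in c("linear", "nonlinear")) {
      f <- fit_t1_pixel(s, paper_angles, 10, method = m)
      expect_true(f$ok)
      expect_lt(abs(f$t1_ms - t1) / t1, 1e-6)
      expect_lt(abs(f$m0 - 100) / 100, 1e-6)
      expect_equal(f$fit_quality, 1, tolerance = 1e-9)
    }
  }
})

test_that("degenerate inputs yield coded failures, not numbers", {
  f <- fit_t1_pixel(rep(0, 8), paper_angles, 10)
  expect_false(f$ok)
  expect_identical(f$reason, "no_signal")
  expect_true(is.na(f$t1_ms))
  # T1 far above the admissible range -> undefined, not clamped
  s <- spgr_signal(100, 50000, 10, paper_angles)
  f2 <- fit_t1_pixel(s, paper_angles, 10, t1_max = 10000)
  expect_false(f2$ok)
  expect_identical(f2$reason, "non_physical")
  expect_error(fit_t1_pixel(1:5, paper_angles, 10), "does not match")
  expect_error(fit_t1_pixel(rep(1, 3), c(10, 10, 10), 10), "degenerate")
})

test_that("linear and nonlinear fits agree on a perturbed signal", {
  s <- spgr_signal(100, 2500, 10, paper_angles)
  s[4] <- s[4] * 1.01
  lin <- fit_t1_pixel(s, paper_angles, 10, method = "linear")
  nl <- fit_t1_pixel(s, paper_angles, 10, method = "nonlinear")
  expect_lt(abs(nl$t1_ms - lin$t1_ms) / lin$t1_ms, 0.03)
  rss <- function(f) sum((s - spgr_signal(f$m0, f$t1_ms, 10, paper_angles))^2)
  expect_lte(rss(nl), rss(lin) + 1e-12)
})

test_that("T1 estimate is scale invariant and m0 scales linearly", {
  s <- spgr_signal(80, 1200, 10, paper_angles)
  base <- fit_t1_pixel(s, paper_angles, 10)
  for (c in c(0.01, 3, 1e4)) {
    f <- fit_t1_pixel(c * s, paper_angles, 10)
    expect_equal(f$t1_ms, base$t1_ms, tolerance = 1e-8)
    expect_equal(f$m0, c * base$m0, tolerance = 1e-8)
  }
})

test_that("map fitting recovers the phantom exactly without noise", {
  p <- small_vfa_protocol()
  g <- small_cylinder(p)
  lab <- rasterize_phantom(g, p)
  tis <- noiseless_tissue()
  ser <- simulate_vfa_series(lab, tis, p, "pre", seed = 1)
  fit <- fit_t1_map(ser)
  for (nm in c("blood", "wall", "perivascular", "background")) {
    code <- c(blood = 1L, wall = 2L, perivascular = 3L, background = 0L)[[nm]]
    got <- fit$t1_ms[lab == code]
    expect_lt(max(abs(got - tis$t1_pre_ms[[nm]])) / tis$t1_pre_ms[[nm]], 1e-6)
  }
  expect_equal(fit$failed_fraction, 0)
  # masked-out pixels stay undefined
  mask <- lab > 0L
  fit2 <- fit_t1_map(ser, mask = mask)
  expect_true(all(is.na(fit2$t1_ms[!mask])))
  expect_error(fit_t1_map(ser, mask = array(FALSE, dim(lab))), "empty mask")
})

test_that("noisy-map medians stay within 2% per compartment at SNR 50", {
  p <- small_vfa_protocol()
  g <- small_cylinder(p)
  lab <- rasterize_phantom(g, p)
  tis <- tissue_params()
  tis$noise_sigma <- vfa_sigma_for_snr(50, m0 = 100, t1_ms = 1900)
  ser <- simulate_vfa_series(lab, tis, p, "pre", seed = 11)
  fit <- fit_t1_map(ser)
  for (nm in c("blood", "wall", "perivascular")) {
    code <- c(blood = 1L, wall = 2L, perivascular = 3L)[[nm]]
    med <- stats::median(fit$t1_ms[lab == code], na.rm = TRUE)
    expect_lt(abs(med - tis$t1_pre_ms[[nm]]) / tis$t1_pre_ms[[nm]], 0.02)
  }
})

test_that("nonlinear refinement matches the linear fit on noiseless input", {
  for (t1 in c(300, 900, 2600)) {
    s <- spgr_signal(50, t1, 10, paper_angles)
    lin <- fit_t1_pixel(s, paper_angles, 10, method = "linear")
    nl <- fit_t1_pixel(s, paper_angles, 10, method = "nonlinear")
    expect_lt(abs(nl$t1_ms - lin$t1_ms) / lin$t1_ms, 1e-4)
  }
})
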