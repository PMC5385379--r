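test_that("rasterized cylinder lumen matches the analytic volume", {
  # radius 1.0 mm at 0.117 mm pixels, as a pure cylinder
  p <- imaging_protocol(6.4, 1.4, c(30, 30, 1), c(256, 256, 6), 30)
  g <- cylinder_geometry(p, radius_mm = 1.0, center_frac = c(0.502, 0.503))
  lab <- rasterize_phantom(g, p)
  vox_mm3 <- prod(p$voxel_mm)
  analytic <- pi * 1.0^2 * p$fov_mm[3]
  counted <- sum(lab == 1L) * vox_mm3
  expect_lt(abs(counted - analytic) / analytic, 0.02)
})

test_that("dilation factor scales the lumen voxel count", {
  p <- small_cine_protocol(nz = 4L, n_frames = 1L)
  g1 <- small_cylinder(p, dilation_factor = 1)
  expect_identical(rasterize_phantom(g1, p, state = "pre"),
                   rasterize_phantom(g1, p, state = "post"))
  # fine grid (0.0625 mm pixels) keeps voxel-count quantization below 2%
  pf <- imaging_protocol(6.4, 1.4, c(12, 12, 0.8), c(192, 192, 4), 30)
  g08 <- small_cylinder(pf, dilation_factor = 0.8)
  pre <- sum(rasterize_phantom(g08, pf, state = "pre") == 1L)
  post <- sum(rasterize_phantom(g08, pf, state = "post") == 1L)
  expect_lt(abs(post / pre - 0.80), 0.02 * 0.80)
})

test_that("lumen count is strictly monotone in the dilation factor", {
  p <- small_cine_protocol(nz = 4L, n_frames = 1L)
  counts <- sapply(c(0.7, 0.9, 1.1, 1.3, 1.5), function(d) {
    g <- small_cylinder(p, dilation_factor = d)
    sum(rasterize_phantom(g, p, state = "post") == 1L)
  })
  expect_true(all(diff(counts) > 0))
})

test_that("compartment counts conserve the voxel total over frames and states", {
  p <- small_cine_protocol(nz = 4L, n_frames = 3L)
  g <- small_cylinder(p, dilation_factor = 0.9, pulsation_amplitude = 0.1)
  for (f in 0:2) for (st in c("pre", "post")) {
    lab <- rasterize_phantom(g, p, frame = f, state = st)
    expect_identical(sum(tabulate(lab + 1L, 4L)), as.integer(prod(p$matrix)))
  }
})

test_that("geometry overflowing the FOV raises a named error", {
  p <- small_cine_protocol(nz = 4L, n_frames = 1L)
  g <- small_cylinder(p, radius_mm = 5.6)
  expect_error(rasterize_phantom(g, p), "does not fit inside")
})

test_that("pulsation makes the lumen smallest at the diastolic frame", {
  p <- small_cine_protocol(nz = 4L, n_frames = 7L)
  g <- small_cylinder(p, pulsation_amplitude = 0.15, diastolic_frame = 4L)
  counts <- sapply(0:6, function(f) sum(rasterize_phantom(g, p, frame = f) == 1L))
  expect_equal(which.min(counts) - 1L, 4L)
})

test_that("magnitude noise background is Rayleigh distributed", {
  set.seed(42)
  x <- add_noise(array(0, dim = c(100, 100)), sigma = 2)
  expect_true(all(x >= 0))
  # Rician with zero signal is Rayleigh; x^2/(2 sigma^2) is then Exp(1)
  ks <- stats::ks.test(as.vector(x)^2 / (2 * 4), "pexp")
  expect_gt(ks$p.value, 0.01)
})

test_that("cine simulation honours the seed contract", {
  p <- small_cine_protocol(nz = 4L, n_frames = 2L)
  g <- small_cylinder(p, dilation_factor = 0.95)
  tis <- tissue_params(); tis$noise_sigma <- 1.5
  a <- simulate_cine(g, tis, p, seed = 7)
  b <- simulate_cine(g, tis, p, seed = 7)
  expect_identical(a$pre$intensities, b$pre$intensities)
  expect_identical(a$post$intensities, b$post$intensities)
  c <- simulate_cine(g, tis, p, seed = 8)
  expect_false(identical(a$pre$intensities, c$pre$intensities))
})

test_that("noiseless identical-geometry cines are voxel-identical pre/post", {
  p <- small_cine_protocol(nz = 4L, n_frames = 2L)
  g <- small_cylinder(p, dilation_factor = 1)
  cines <- simulate_cine(g, noiseless_tissue(), p, seed = 1)
  expect_identical(cines$pre$intensities, cines$post$intensities)
})
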