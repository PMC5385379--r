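make_disk_image <- function(n = 40, cx = 20, cy = 20, r = 10, hi = 1, lo = 0) {
  img <- matrix(lo, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - cx)^2 + (j - cy)^2 <= r^2) img[i, j] <- hi
  img
}

test_that("disk segmentation recovers the analytic area", {
  img <- make_disk_image()
  for (m in c("fraction", "otsu")) {
    seg <- segment_lumen_slice(img, c(1, 1), seed_point = c(19, 19), method = m)
    expect_lt(abs(seg$area_mm2 - pi * 100) / (pi * 100), 0.05)
  }
  expect_error(segment_lumen_slice(matrix(1, 10, 10), c(1, 1), c(5, 5)),
               "constant")
})

test_that("the seeded connected component is retained and holes filled", {
  img <- make_disk_image(cx = 12, cy = 12, r = 6) +
    make_disk_image(cx = 30, cy = 30, r = 6)
  seg_l <- segment_lumen_slice(img, c(1, 1), seed_point = c(11, 11))
  seg_r <- segment_lumen_slice(img, c(1, 1), seed_point = c(29, 29))
  expect_false(any(seg_l$mask & seg_r$mask))
  expect_equal(seg_l$area_mm2, seg_r$area_mm2)
  holed <- make_disk_image()
  holed[20, 20] <- 0
  seg <- segment_lumen_slice(holed, c(1, 1), seed_point = c(15, 20))
  expect_true(seg$mask[20, 20])   # hole filled
})

test_that("segmented area is non-increasing in the threshold fraction", {
  set.seed(4)
  img <- make_disk_image(hi = 100, lo = 10) + matrix(rnorm(1600, 0, 3), 40, 40)
  areas <- sapply(seq(0.2, 0.8, by = 0.1), function(fr)
    segment_lumen_slice(img, c(1, 1), c(19, 19), fraction = fr)$area_mm2)
  expect_true(all(diff(areas) <= 0))
})

test_that("segmentation is invariant to 90-degree rotation", {
  set.seed(5)
  img <- make_disk_image(cx = 17, cy = 23, r = 9, hi = 100, lo = 10) +
    matrix(rnorm(1600, 0, 2), 40, 40)
  seg <- segment_lumen_slice(img, c(1, 1), c(16, 22))
  rot <- t(img)[ncol(img):1, ]                      # 90 deg CCW
  seg_r <- segment_lumen_slice(rot, c(1, 1), c(40 - 23, 16))
  expect_equal(seg$area_mm2, seg_r$area_mm2)
})

test_that("the diastolic frame minimizes the segmented lumen area", {
  p <- small_cine_protocol(nz = 6L, n_frames = 7L)
  g <- small_cylinder(p, pulsation_amplitude = 0.15, diastolic_frame = 4L)
  cines <- simulate_cine(g, noiseless_tissue(), p, seed = 1)
  expect_equal(select_diastolic_frame(cines$pre, seed_point = c(49, 46)), 4L)
  # constant radius: ties break to the lowest frame index
  g0 <- small_cylinder(p, pulsation_amplitude = 0)
  cines0 <- simulate_cine(g0, noiseless_tissue(), p, seed = 1)
  expect_equal(select_diastolic_frame(cines0$pre, seed_point = c(49, 46)), 0L)
  # single-frame cine trivially returns frame 0
  p1 <- small_cine_protocol(nz = 4L, n_frames = 1L)
  c1 <- simulate_cine(small_cylinder(p1), noiseless_tissue(), p1, seed = 1)
  expect_equal(select_diastolic_frame(c1$pre, seed_point = c(49, 46)), 0L)
})

test_that("analysis slices end strictly before the branch", {
  p <- small_cine_protocol(nz = 16L, n_frames = 1L)
  g <- default_geometry(p, radius_mm = 1.0, branch_slice = 12L,
                        slant_mm_per_slice = c(0.02, 0.01),
                        taper_per_slice = 0.005, diastolic_frame = 0L)
  cines <- simulate_cine(g, noiseless_tissue(), p, seed = 1)
  seed_pt <- c(48, 48)
  expect_equal(select_analysis_slices(cines$pre, seed_pt), 7:11)
  expect_equal(select_analysis_slices(cines$pre, seed_pt, override = 3:7), 3:7)
  expect_error(select_analysis_slices(cines$pre, seed_pt, override = 12:16),
               "outside")
  # branch too close to the stack base
  g2 <- default_geometry(p, radius_mm = 1.0, branch_slice = 3L,
                         slant_mm_per_slice = c(0.02, 0.01),
                         taper_per_slice = 0.005, diastolic_frame = 0L)
  cines2 <- simulate_cine(g2, noiseless_tissue(), p, seed = 1)
  expect_error(select_analysis_slices(cines2$pre, seed_pt), "proximal")
  # no branch at all
  g3 <- small_cylinder(small_cine_protocol(nz = 8L, n_frames = 1L))
  cines3 <- simulate_cine(g3, noiseless_tissue(),
                          small_cine_protocol(nz = 8L, n_frames = 1L), seed = 1)
  expect_error(select_analysis_slices(cines3$pre, seed_pt), "no branch")
})

test_that("volume reconstruction and percent change are exact arithmetic", {
  expect_equal(reconstruct_volume(2, 0.167), 0.334)
  expect_equal(reconstruct_volume(c(1, 2, 3), 0.5), 3)
  expect_error(reconstruct_volume(numeric(0), 0.1), "at least one")
  expect_equal(volume_change_percent(1, 1), 0)
  expect_equal(volume_change_percent(1.000, 0.9282), -7.18, tolerance = 1e-12)
  expect_equal(volume_change_percent(1.000, 1.093), 9.3, tolerance = 1e-12)
  expect_error(volume_change_percent(0, 1), "v_pre")
})

test_that("segmented cylinder volume matches the analytic value", {
  p <- small_cine_protocol(nz = 6L, n_frames = 1L)
  g <- small_cylinder(p, radius_mm = 1.2)
  # wall/rim at background intensity puts the half-way threshold exactly on
  # the lumen boundary, so the count is an unbiased area estimate
  tis <- noiseless_tissue(cine_intensity = c(blood = 100, wall = 10,
                                             perivascular = 10,
                                             background = 10))
  cines <- simulate_cine(g, tis, p, seed = 1)
  seg <- endoprofile:::track_segment_stack(cines$pre$intensities[, , , 1],
                                           0:5, p$voxel_mm[1:2], c(49, 46))
  v <- reconstruct_volume(seg$areas, p$voxel_mm[3])
  analytic <- pi * 1.2^2 * p$fov_mm[3]
  expect_lt(abs(v - analytic) / analytic, 0.02)
})

test_that("the full vasomotion pipeline recovers a scaled-down response", {
  p <- small_cine_protocol(nz = 16L, n_frames = 3L)
  g <- default_geometry(p, radius_mm = 1.0, branch_slice = 12L,
                        slant_mm_per_slice = c(0.02, 0.01),
                        taper_per_slice = 0.005, dilation_factor = 0.90,
                        diastolic_frame = 1L)
  cines <- simulate_cine(g, noiseless_tissue(), p, seed = 2)
  vr <- measure_vasomotion(cines$pre, cines$post, seed_point = c(48, 48))
  expect_lt(abs(vr$percent_change - (-10)), 1.0)
  expect_equal(vr$slices, 7:11)
  expect_equal(vr$diastolic_frame_pre, 1L)
})
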