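# brute-force rim: pixels within city-block (or chessboard) distance t of
# any lumen pixel, minus the lumen
rim_oracle <- function(lumen, t, connectivity = 4) {
  on <- which(lumen, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(lumen), ncol(lumen))
  for (i in seq_len(nrow(lumen))) for (j in seq_len(ncol(lumen))) {
    d <- if (connectivity == 4) abs(on[, 1] - i) + abs(on[, 2] - j)
         else pmax(abs(on[, 1] - i), abs(on[, 2] - j))
    if (min(d) <= t) out[i, j] <- TRUE
  }
  out & !lumen
}

test_that("perivascular ROI is the dilation ring around the lumen", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  roi <- perivascular_roi(m, 1, connectivity = 4)
  expect_equal(sum(roi), 4L)
  expect_false(any(roi & m))

  disk <- matrix(FALSE, 21, 21)
  for (i in 1:21) for (j in 1:21)
    if ((i - 11)^2 + (j - 11)^2 <= 25) disk[i, j] <- TRUE
  for (conn in c(4, 8)) {
    roi2 <- perivascular_roi(disk, 2, connectivity = conn)
    expect_identical(roi2, rim_oracle(disk, 2, conn))
  }
  expect_error(perivascular_roi(disk, 0), "rim_thickness")
  expect_error(perivascular_roi(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("relative T1 change follows the baseline-referenced definition", {
  pre <- matrix(1200, 3, 3); post <- matrix(1200, 3, 3)
  expect_equal(relative_t1_change(pre, post), matrix(0, 3, 3))
  post[1, 1] <- 500; post[2, 2] <- 600
  ch <- relative_t1_change(pre, post)
  expect_equal(ch[1, 1], (1200 - 500) / 1200)
  expect_equal(ch[2, 2], 0.5)
  expect_error(relative_t1_change(pre, matrix(1, 2, 2)), "shapes")
})

test_that("Npx50 counts strict exceedances only", {
  pre <- matrix(1200, 4, 4); post <- matrix(1200, 4, 4)
  roi <- matrix(TRUE, 4, 4)
  expect_equal(compute_npx50(pre, post, roi)$npx50, 0L)
  post[1, 1] <- 600          # exactly 50%: boundary, not counted
  post[2, 1] <- 599          # just above threshold
  res <- compute_npx50(pre, post, roi, threshold = 0.5)
  expect_equal(res$npx50, 1L)
  expect_true(res$changed_mask[2, 1])
  expect_false(res$changed_mask[1, 1])
})

test_that("Npx50 is scale invariant and monotone in the threshold", {
  set.seed(3)
  pre <- matrix(runif(64 * 64, 800, 2000), 64, 64)
  post <- pre * matrix(runif(64 * 64, 0.2, 1.1), 64, 64)
  roi <- matrix(runif(64 * 64) < 0.4, 64, 64)
  base <- compute_npx50(pre, post, roi)$npx50
  for (c in c(0.05, 7)) {
    expect_equal(compute_npx50(c * pre, c * post, roi)$npx50, base)
  }
  counts <- sapply(seq(0.1, 0.9, by = 0.1), function(th)
    compute_npx50(pre, post, roi, threshold = th)$npx50)
  expect_true(all(diff(counts) <= 0))
})

test_that("Npx50 equals an exhaustive per-pixel loop", {
  set.seed(9)
  pre <- matrix(runif(64 * 64, 500, 2500), 64, 64)
  post <- pre * matrix(runif(64 * 64, 0.1, 1.2), 64, 64)
  pre[sample(64 * 64, 100)] <- NA
  post[sample(64 * 64, 100)] <- NA
  roi <- matrix(runif(64 * 64) < 0.5, 64, 64)
  res <- compute_npx50(pre, post, roi, threshold = 0.5)
  count <- 0L; evaluable <- 0L
  for (i in 1:64) for (j in 1:64) {
    if (!roi[i, j]) next
    if (is.na(pre[i, j]) || is.na(post[i, j])) next
    evaluable <- evaluable + 1L
    if ((pre[i, j] - post[i, j]) / pre[i, j] > 0.5) count <- count + 1L
  }
  expect_equal(res$npx50, count)
  expect_equal(res$roi_size, evaluable)
})

test_that("undefined pixels are excluded, and an all-undefined ROI errors", {
  pre <- matrix(NA_real_, 4, 4); post <- matrix(1, 4, 4)
  roi <- matrix(TRUE, 4, 4)
  expect_error(compute_npx50(pre, post, roi), "no evaluable pixels")
  expect_error(compute_npx50(post, post, matrix(FALSE, 4, 4)), "empty")
})

test_that("leak fraction round-trips through T1 fitting into Npx50", {
  p <- small_vfa_protocol()
  g <- small_cylinder(p)
  lab <- rasterize_phantom(g, p)
  rim <- lab == 3L
  n_rim <- sum(rim)
  for (f in c(0.1, 0.5)) {
    tis <- noiseless_tissue(leak_fraction = f)
    pre <- simulate_vfa_series(lab, tis, p, "pre", seed = 2)
    post <- simulate_vfa_series(lab, tis, p, "post", seed = 3)
    res <- compute_npx50(fit_t1_map(pre), fit_t1_map(post), rim)
    expect_equal(res$npx50, round(f * n_rim))
  }
})
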