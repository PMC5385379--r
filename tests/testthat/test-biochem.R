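mini_panel <- function() {
  ids <- c("a1", "a2")
  do.call(rbind, lapply(list(
    c("Ang-(1-7)", 60, 25), c("Ang II", 120, 25),
    c("L-Arg", 100, 80), c("ADMA", 1, 0)), function(x)
      data.frame(animal_id = ids, group = "G", analyte = x[1],
                 concentration = as.numeric(x[2:3]),
                 units = "u", stringsAsFactors = FALSE)))
}

test_that("per-animal ratios are derived and zero denominators flagged", {
  panel <- mini_panel()
  aug <- derive_ratios(panel)
  r17 <- aug[aug$analyte == "Ang-(1-7)/Ang II", ]
  expect_equal(r17$concentration[r17$animal_id == "a1"], 0.5)
  expect_equal(r17$concentration[r17$animal_id == "a2"], 1)
  rla <- aug[aug$analyte == "L-Arg/ADMA", ]
  expect_equal(rla$concentration[rla$animal_id == "a1"], 100)
  expect_true(is.na(rla$concentration[rla$animal_id == "a2"]))
  expect_match(attr(aug, "undefined_ratios"), "a2")
  # missing analyte names the animal and analyte
  broken <- panel[!(panel$animal_id == "a2" & panel$analyte == "ADMA"), ]
  expect_error(derive_ratios(broken), "a2.*ADMA")
})

test_that("group percent change uses the requested location estimator", {
  panel <- data.frame(
    animal_id = sprintf("x%d", 1:6),
    group = rep(c("ref", "trt"), each = 3),
    analyte = "Ang II",
    concentration = c(119.8, 119.8, 119.8, 50.2, 50.2, 50.2),
    units = "fmol/ml", stringsAsFactors = FALSE)
  expect_equal(group_percent_change(panel, "Ang II", "ref", "trt"),
               100 * (50.2 - 119.8) / 119.8, tolerance = 1e-12)
  expect_equal(group_percent_change(panel, "Ang II", "ref", "ref"), 0)
  npx <- data.frame(animal_id = sprintf("y%d", 1:6),
                    group = rep(c("ref", "trt"), each = 3),
                    analyte = "Npx50",
                    concentration = c(14, 15, 16, 5, 6, 7),
                    units = "pixels", stringsAsFactors = FALSE)
  expect_equal(group_percent_change(npx, "Npx50", "ref", "trt",
                                    location = "median"), -60)
})

test_that("Kruskal-Wallis matches the brute-force rank statistic", {
  kt <- compare_groups(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(kt$statistic, kw_oracle(1:9, rep(c("a", "b", "c"), each = 3)),
               tolerance = 1e-10)
  set.seed(10)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    g <- sample(letters[1:3], n, replace = TRUE)
    while (min(table(factor(g, levels = letters[1:3]))) < 2)
      g <- sample(letters[1:3], n, replace = TRUE)
    v <- sample(1:5, n, replace = TRUE)   # heavy ties
    if (stats::sd(v) == 0) next
    kt <- compare_groups(v, g)
    expect_equal(kt$statistic, kw_oracle(v, g), tolerance = 1e-10)
  }
})

test_that("identical groups give a null omnibus result", {
  v <- rep(5, 9); g <- rep(c("a", "b", "c"), each = 3)
  for (design in c("nonparametric", "parametric")) {
    r <- compare_groups(v, g, design)
    expect_equal(r$statistic, 0)
    expect_equal(r$p_value, 1, tolerance = 1e-12)
  }
})

test_that("post-hoc tables appear only for three or more groups", {
  set.seed(2)
  v <- c(rnorm(5), rnorm(5, 2), rnorm(5, 4))
  g <- rep(c("a", "b", "c"), each = 5)
  r3 <- compare_groups(v, g)
  expect_s3_class(r3$posthoc, "data.frame")
  expect_equal(nrow(r3$posthoc), 3L)
  expect_true(all(r3$posthoc$p_adjusted >= r3$posthoc$p_value - 1e-15))
  r2 <- compare_groups(v[1:10], g[1:10])
  expect_null(r2$posthoc)
  ra <- compare_groups(v, g, "parametric")
  expect_equal(nrow(ra$posthoc), 3L)
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
})

test_that("Spearman correlation equals Pearson on average ranks", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x^3)$r, -1)
  y <- c(2, 1, 4, 3, 5)
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(correlate(x, y)$r, oracle, tolerance = 1e-12)
  set.seed(6)
  xt <- sample(1:4, 30, replace = TRUE)   # ties
  yt <- xt + sample(0:2, 30, replace = TRUE)
  expect_equal(correlate(xt, yt)$r, stats::cor(rank(xt), rank(yt)),
               tolerance = 1e-12)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(correlate(1:2, 1:2), "n >= 3")
})

test_that("cohort profile reproduces the published correlation sign pattern", {
  cohort <- simulate_study_cohort("2-month", seed = 7)
  prof <- profile_cohort(cohort$imaging, cohort$panel)
  cors <- prof$correlations
  get_r <- function(pat) cors$r_spearman[grepl(pat, cors$pair)]
  expect_lt(get_r("BCA volume change and Npx50"), 0)
  expect_gt(get_r("BCA volume change and L-Arg/ADMA"), 0)
  expect_gt(get_r("BCA volume change and Ang-\\(1-7\\)/Ang II"), 0)
  expect_lt(get_r("Npx50 and L-Arg/ADMA"), 0)
  expect_lt(get_r("Npx50 and Ang-\\(1-7\\)/Ang II"), 0)
})

test_that("cohort profile is invariant to animal order and rejects orphans", {
  cohort <- simulate_study_cohort("2-month", seed = 3)
  prof1 <- profile_cohort(cohort$imaging, cohort$panel)
  shuf <- cohort$imaging[sample(nrow(cohort$imaging)), ]
  pshuf <- cohort$panel[rev(seq_len(nrow(cohort$panel))), ]
  prof2 <- profile_cohort(shuf, pshuf)
  expect_equal(prof1$correlations, prof2$correlations)
  expect_equal(prof1$group_summary, prof2$group_summary)
  bad <- cohort$imaging
  bad$animal_id[1] <- "ghost"
  expect_error(profile_cohort(bad, cohort$panel), "ghost")
  one <- cohort$imaging[1, ]
  onep <- cohort$panel[cohort$panel$animal_id == one$animal_id, ]
  expect_error(profile_cohort(one, onep), "n >= 3")
})
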