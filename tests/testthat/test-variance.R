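test_that("Brown-Forsythe matches the hand-worked two-group instance", {
  y <- c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10)
  g <- factor(rep(c("A", "B"), each = 5))
  # medians 3 and 6; deviations {2,1,0,1,2} and {4,2,0,2,4}
  res <- brown_forsythe_test(y, g)
  expect_equal(round(res$statistic, 3), 2.057)
  expect_equal(res$df, c(1L, 8L))

  map <- brown_forsythe_map(matrix(y, ncol = 1), g)
  expect_equal(map$statistic[1], res$statistic, tolerance = 1e-12)
  expect_equal(map$p[1], res$p, tolerance = 1e-12)
})

test_that("Brown-Forsythe is invariant to location shifts and global rescaling", {
  set.seed(4)
  a <- rnorm(9)
  g <- factor(rep(c("A", "B", "C"), each = 3))
  y <- c(a[1:3], a[4:6] + 100, a[7:9] - 42)
  y0 <- c(a[1:3], a[4:6], a[7:9])
  f_shift <- brown_forsythe_map(matrix(y, ncol = 1), g)$statistic
  f_base <- brown_forsythe_map(matrix(y0, ncol = 1), g)$statistic
  expect_equal(f_shift, f_base, tolerance = 1e-10)
  f_scale <- brown_forsythe_map(matrix(y * 1e3, ncol = 1), g)$statistic
  expect_equal(f_scale, f_base, tolerance = 1e-10)

  # a pure location shift between groups gives F = 0
  same <- rep(c(1, 2, 3, 4, 5), 2) + rep(c(0, 7), each = 5)
  f0 <- brown_forsythe_map(matrix(same, ncol = 1),
                           factor(rep(c("A", "B"), each = 5)))$statistic
  expect_equal(f0, 0)
})

test_that("vectorized map equals the scalar reference on random voxels", {
  set.seed(1)
  g <- factor(rep(c("a", "b", "c"), c(16, 23, 33)))
  x <- matrix(rnorm(72 * 1000), 72)
  map <- brown_forsythe_map(x, g)
  ref_f <- vapply(seq_len(1000), function(j)
    brown_forsythe_test(x[, j], g)$statistic, 0)
  ref_p <- vapply(seq_len(1000), function(j)
    brown_forsythe_test(x[, j], g)$p, 0)
  expect_lt(max(abs(map$statistic - ref_f)), 1e-10)
  expect_lt(max(abs(map$p - ref_p)), 1e-10)
})

test_that("degenerate voxels are flagged with p = 1", {
  g <- factor(rep(c("a", "b"), each = 4))
  x <- cbind(rep(1, 8), rnorm(8))
  map <- brown_forsythe_map(x, g)
  expect_true(map$degenerate[1])
  expect_equal(map$p[1], 1)
  expect_false(map$degenerate[2])
})

test_that("type-I error stays near nominal for Gaussian and skewed data", {
  set.seed(12)
  g <- factor(rep(c("a", "b"), c(16, 33)))
  x <- matrix(rnorm(49 * 4000), 49)
  expect_gt(mean(brown_forsythe_map(x, g)$p < 0.05), 0.035)
  expect_lt(mean(brown_forsythe_map(x, g)$p < 0.05), 0.065)
  xs <- matrix(exp(rnorm(49 * 4000)), 49)
  r <- mean(brown_forsythe_map(xs, g)$p < 0.05)
  expect_gt(r, 0.03); expect_lt(r, 0.07)
})

test_that("power rises monotonically with the planted variance ratio", {
  set.seed(6)
  g <- factor(rep(c("a", "b"), c(16, 33)))
  power_at <- vapply(c(1, 1.5, 2, 3), function(ratio) {
    x <- rbind(matrix(rnorm(16 * 3000, sd = ratio), 16),
               matrix(rnorm(33 * 3000), 33))
    mean(brown_forsythe_map(x, g)$p < 0.05)
  }, 0)
  expect_true(all(diff(power_at) > 0))
})

test_that("residualize removes covariate variance but keeps group structure", {
  set.seed(10)
  n <- 72
  g <- factor(rep(c("deaf", "hearing"), c(39, 33)))
  age <- rnorm(n, ifelse(g == "deaf", 24, 21), 2)
  y <- outer(2 * age, rep(1, 200)) +
    outer(ifelse(g == "deaf", 0.3, 0), rep(1, 200)) +
    matrix(rnorm(n * 200), n)
  des <- group_design(sprintf("s%02d", 1:n), g, cbind(age = age))
  res <- residualize(y, des)
  agec <- age - ave(age, g)
  pcor <- apply(res, 2, function(col) cor(col - ave(col, g), agec))
  expect_lt(mean(abs(pcor)), 0.02)

  # noise-free construction: the group effect is retained exactly
  y_exact <- outer(2 * age, rep(1, 3)) +
    outer(ifelse(g == "deaf", 0.3, 0), rep(1, 3))
  res_exact <- residualize(y_exact, des)
  expect_equal(unname(colMeans(res_exact[g == "deaf", ]) -
                        colMeans(res_exact[g == "hearing", ])),
               rep(0.3, 3), tolerance = 1e-10)

  # covariate orthogonal to the data leaves it unchanged
  y2 <- matrix(rnorm(n * 50), n)
  orth <- qr.resid(qr(cbind(1, stats::model.matrix(~0 + g), y2)), rnorm(n))
  des2 <- group_design(sprintf("s%02d", 1:n), g, cbind(o = orth))
  expect_lt(max(abs(residualize(y2[, 1:5], des2) - y2[, 1:5])), 1e-10)

  # no covariates: identity
  des3 <- group_design(sprintf("s%02d", 1:n), g)
  expect_identical(residualize(y2, des3), y2)

  # collinear design errors with the offending column named
  des4 <- group_design(sprintf("s%02d", 1:n), g,
                       cbind(age = age, age2 = 2 * age))
  expect_error(residualize(y2, des4), "age2")
})

test_that("variability ratios invert under group swap and behave under null", {
  set.seed(14)
  g <- factor(rep(c("deaf", "hearing"), c(16, 33)))
  x <- rbind(matrix(rnorm(16 * 2000), 16), matrix(rnorm(33 * 2000), 33))
  r1 <- variability_ratio_map(x, g, "deaf", "hearing", restrict = 1:2000)
  r2 <- variability_ratio_map(x, g, "hearing", "deaf", restrict = 1:2000)
  expect_equal(r1$ratio, 1 / r2$ratio, tolerance = 1e-12)
  expect_gt(median(r1$ratio, na.rm = TRUE), 0.8)
  expect_lt(median(r1$ratio, na.rm = TRUE), 1.25)

  # variance option squares the SD ratio
  rv <- variability_ratio_map(x, g, "deaf", "hearing", restrict = 1:2000,
                              spread = "var")
  expect_equal(rv$ratio, r1$ratio^2, tolerance = 1e-12)

  # zero-denominator voxels are flagged and excluded
  x2 <- x
  x2[g == "hearing", 1] <- 0
  r3 <- variability_ratio_map(x2, g, "deaf", "hearing", restrict = 1:5)
  expect_equal(r3$flagged, 1L)
  expect_true(is.na(r3$ratio[1]))
})

test_that("Levene (mean-centered) variant is available but not the default", {
  y <- c(1, 2, 3, 4, 100, 2, 4, 6, 8, 10)
  g <- factor(rep(c("A", "B"), each = 5))
  f_med <- brown_forsythe_map(matrix(y), g)$statistic
  f_mean <- brown_forsythe_map(matrix(y), g, center = "mean")$statistic
  expect_false(isTRUE(all.equal(f_med, f_mean)))
})
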