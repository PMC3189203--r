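test_that("linear detrending removes exactly linear components", {
  tt <- 1:50
  expect_equal(linear_detrend(3 + 0.5 * tt), rep(0, 50), tolerance = 1e-10)
  expect_equal(linear_detrend(rep(4, 50)), rep(0, 50), tolerance = 1e-12)
  set.seed(1)
  y <- rnorm(80)
  res <- linear_detrend(y)
  # residuals orthogonal to intercept and slope (normal equations)
  expect_lt(abs(sum(res)), 1e-10)
  expect_lt(abs(sum(res * (1:80))), 1e-8)
  expect_error(linear_detrend(1), "at least 2")
  # matrix input detrends per column
  m <- cbind(1:30, rep(2, 30))
  expect_equal(linear_detrend(m), matrix(0, 30, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("high-pass filter separates frequencies around the cutoff", {
  n <- 660; tr <- 2
  tt <- (seq_len(n) - 1) * tr
  expect_equal(highpass(rep(5, n), tr_s = tr), rep(0, n), tolerance = 1e-8)
  rms <- function(x) sqrt(mean(x^2))
  slow <- sin(2 * pi * 0.002 * tt)
  fast <- sin(2 * pi * 0.05 * tt)
  expect_lt(rms(highpass(slow, 0.01, tr)) / rms(slow), 0.10)
  expect_gt(rms(highpass(fast, 0.01, tr)) / rms(fast), 0.90)
  expect_error(highpass(slow, cutoff_hz = 0.3, tr_s = 2), "Nyquist")
})

test_that("Gaussian smoothing conserves totals and respects symmetry", {
  vol <- array(7, c(8, 8, 8))
  sm <- gaussian_smooth(vol)
  expect_equal(sm, vol, tolerance = 1e-10, ignore_attr = TRUE)
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  smi <- gaussian_smooth(imp)
  expect_equal(which.max(smi), which.max(imp))
  expect_equal(smi[4, 5, 5], smi[6, 5, 5])
  expect_equal(smi[5, 4, 5], smi[5, 6, 5])
  # total conserved under reflective boundary, vs dense convolution oracle
  set.seed(2)
  r <- array(rnorm(6 * 7 * 5), c(6, 7, 5))
  smr <- gaussian_smooth(r, fwhm_mm = 6)
  expect_equal(sum(smr), sum(r), tolerance = 1e-6)
  # dense oracle: explicit triple loop with symmetric reflection
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  rad <- ceiling(3 * sigma)
  k1 <- dnorm(-rad:rad, sd = sigma); k1 <- k1 / sum(k1)
  refl <- function(i, n) { m <- (i - 1) %% (2 * n); ifelse(m < n, m + 1, 2 * n - m) }
  oracle <- array(0, dim(r))
  for (x in 1:6) for (y in 1:7) for (z in 1:5) {
    acc <- 0
    for (dx in -rad:rad) for (dy in -rad:rad) for (dz in -rad:rad) {
      acc <- acc + k1[dx + rad + 1] * k1[dy + rad + 1] * k1[dz + rad + 1] *
        r[refl(x + dx, 6), refl(y + dy, 7), refl(z + dz, 5)]
    }
    oracle[x, y, z] <- acc
  }
  expect_equal(smr, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("voxelwise z-scoring normalizes and flags degenerate voxels", {
  z <- zscore_voxelwise(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  m <- cbind(rnorm(20, 5, 3), rep(2, 20), rnorm(20))
  zm <- zscore_voxelwise(m)
  expect_equal(attr(zm, "degenerate"), 2L, ignore_attr = TRUE)
  expect_equal(zm[, 2], rep(0, 20))
  expect_lt(max(abs(colMeans(zm[, c(1, 3)]))), 1e-12)
  expect_equal(apply(zm[, c(1, 3)], 2, sd), c(1, 1), tolerance = 1e-12)
})

test_that("ROI t-value matches the pooled two-sample oracle", {
  expect_equal(roi_t_value(c(1, 1, 1, 1, 1)), 0)
  # oracle: means 2 vs 5, pooled variance 4/3 on 3 df
  x <- c(1, 3, 4, 6, 5)
  oracle <- (5 - 2) / sqrt((4 / 3) * (1 / 2 + 1 / 3))
  expect_equal(roi_t_value(x), oracle, tolerance = 1e-12)
  expect_equal(round(roi_t_value(x), 3), 2.846)
  # affine invariance
  expect_equal(roi_t_value(2.5 * x + 7), roi_t_value(x), tolerance = 1e-12)
  expect_error(roi_t_value(1:4), "5 post-offer scans")
  expect_warning(t_cap <- roi_t_value(c(1, 1, 2, 2, 2)), "capped")
  expect_equal(t_cap, 1e6)
})

test_that("feature vectors have one t-value per pooled ROI", {
  sig <- cbind(LPFC = c(0, 0, 3, 3, 3), AI = rep(1, 5), OC = c(2, 0, 1, 1, 1))
  # the noiseless LPFC column has zero pooled variance with a nonzero
  # difference, which is reported and capped
  expect_warning(f <- compute_feature_vector(sig), "capped")
  expect_equal(length(f), 3)
  expect_named(f, c("LPFC", "AI", "OC"))
  expect_equal(unname(f["AI"]), 0)
  expect_gt(f[["LPFC"]], 0)
  # zero-signal trial gives exactly zero features
  f0 <- compute_feature_vector(matrix(5, 5, 3,
                                      dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(unname(f0), c(0, 0, 0))
})

test_that("null t-features follow a Student t distribution with 3 df", {
  set.seed(4)
  n <- 1e4
  tvals <- apply(matrix(rnorm(5 * n), ncol = 5), 1, roi_t_value)
  ks <- suppressWarnings(ks.test(tvals, pt, df = 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("trial averaging takes the mean of post-offer scans 2-4", {
  v <- array(rep(1:5, each = 8), c(2, 2, 2, 5))
  avg <- trial_average_volume(v)
  expect_equal(avg, array(3, c(2, 2, 2)))
  m <- matrix(rep(1:5, each = 4), nrow = 4)
  expect_equal(trial_average_volume(m), rowMeans(m[, 2:4]))
  same <- array(2, c(2, 2, 2, 4))
  expect_equal(trial_average_volume(same), array(2, c(2, 2, 2)))
  expect_error(trial_average_volume(array(0, c(2, 2, 2, 3))), "at least 4")
  # elementwise oracle
  set.seed(5)
  r <- array(rnorm(2 * 2 * 2 * 6), c(2, 2, 2, 6))
  oracle <- (r[, , , 2] + r[, , , 3] + r[, , , 4]) / 3
  expect_equal(trial_average_volume(r), oracle, tolerance = 1e-12)
})

test_that("trial scan indexing counts from the offer onset", {
  expect_equal(trial_scan_indices(1), 2:6)
  expect_equal(trial_scan_indices(2), 13:17)
  expect_equal(trial_scan_indices(60)[5], 655)
  idx <- trial_scan_indices(1:3)
  expect_equal(dim(idx), c(3, 5))
})
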