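test_that("feature selection keeps exactly the voxels beyond the threshold", {
  y <- rep(0:1, each = 20)
  x <- sapply(c(0.0, 0.1, 0.2, 0.9), function(r)
    planted_cor_column(y, r, seed = round(100 * r) + 1))
  # brute-force Pearson oracle confirms the planted correlations
  expect_equal(as.numeric(abs(cor(x, y))), c(0.0, 0.1, 0.2, 0.9),
               tolerance = 1e-10)
  expect_equal(select_features(x, y, threshold = 0.15), c(3L, 4L))
  # a voxel identical to the labels has r = 1 and is kept
  x2 <- cbind(x, as.numeric(y))
  expect_true(5L %in% select_features(x2, y))
  # constant voxels are excluded
  x3 <- cbind(x, 1)
  expect_false(5L %in% select_features(x3, y))
  # the closed boundary |r| = 0.15 is excluded
  x4 <- cbind(planted_cor_column(y, 0.15, 7), planted_cor_column(y, 0.16, 8))
  expect_equal(select_features(x4, y, threshold = 0.15), 2L)
  expect_error(select_features(x[, 1, drop = FALSE], y), "no voxel passed")
})

test_that("correct prediction rate is a percentage of matches", {
  expect_equal(correct_prediction_rate(c(1, 0, 1, 1), c(1, 0, 0, 1)), 75)
  expect_equal(correct_prediction_rate(rep(1, 5), rep(1, 5)), 100)
  p <- c(1, 1, 0, 0); t <- c(1, 0, 0, 1)
  expect_equal(correct_prediction_rate(p, t),
               100 - correct_prediction_rate(1 - p, t))
  # invariant to jointly swapping labels
  expect_equal(correct_prediction_rate(p, t),
               correct_prediction_rate(1 - p, 1 - t))
  expect_error(correct_prediction_rate(integer(0), integer(0)), "empty")
})

test_that("linear SVM weight extraction agrees with the reference predictions", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40, -1), 20, 2), matrix(rnorm(40, 1), 20, 2))
  y <- rep(0:1, each = 20)
  m <- fit_linear_svm(x, y)
  ref <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = 1, scale = FALSE)
  grid_pts <- as.matrix(expand.grid(seq(-2, 2, 0.5), seq(-2, 2, 0.5)))
  expect_equal(predict_linear_svm(m, grid_pts),
               as.integer(as.character(predict(ref, grid_pts))))
  # resubstitution agreement on the training data too
  expect_equal(predict_linear_svm(m, x),
               as.integer(as.character(predict(ref, x))))
})

test_that("LOOCV separates planted effects and stays at chance on null data", {
  set.seed(11)
  n <- 30; p <- 60
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1:8] <- x[, 1:8] + 3 * y  # strong planted effect
  expect_equal(loocv(x, y)$accuracy, 100)
  # pure noise, permuted labels: mean accuracy within 3 SE of 50%
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    xn <- matrix(rnorm(n * p), n, p)
    yn <- sample(y)
    loocv(xn, yn)$accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * se + 1e-9)
})

test_that("feature selection inside LOOCV never reads the held-out sample", {
  # crafted input: voxel 1 passes the threshold only because of sample 1
  y <- rep(0:1, each = 10)
  v <- planted_cor_column(y, 0.05, seed = 3)
  v[1] <- v[1] - 30  # outlier in the reject class drags |r| above threshold
  x <- cbind(v, planted_cor_column(y, 0.5, seed = 4))
  sel_all <- select_features(x, y)
  sel_fold <- select_features(x[-1, ], y[-1])
  expect_true(1L %in% sel_all)
  expect_false(1L %in% sel_fold)
})

test_that("cross-subject transfer works only for shared codes", {
  grid <- test_small_grid()
  cl <- data.frame(x = 0, y = 0, z = 0, radius_mm = 7)
  shared <- simulate_sample_matrix(grid, cl, signal = "choice",
                                   amplitude = 3, noise_sd = 0.05,
                                   n_subjects = 3, seed = 21)
  res <- leave_one_subject_out(shared$x, shared$meta$choice,
                               shared$meta$subject)
  expect_equal(nrow(res), 3)
  expect_true(all(res$accuracy == 100))
  expect_equal(sum(res$n_trials), 180)
  # subject-unique codes must not transfer
  uniq <- simulate_sample_matrix(grid, cl, signal = "choice",
                                 amplitude = 1.2, noise_sd = 1,
                                 n_subjects = 4, subject_specific = TRUE,
                                 seed = 22)
  res_u <- leave_one_subject_out(uniq$x, uniq$meta$choice,
                                 uniq$meta$subject)
  expect_lt(mean(res_u$accuracy), 62)
  expect_gt(mean(res_u$accuracy), 38)
})

test_that("balanced subsets equalize the four label cells", {
  choice <- rep(c(1, 1, 0, 0), c(19, 30, 40, 50))
  value <- rep(c(1, 0, 1, 0), c(19, 30, 40, 50))
  subs <- balanced_subsets(choice, value, n_subsets = 25, seed = 2)
  expect_length(subs, 25)
  for (s in subs[1:5]) {
    expect_length(s, 76)  # 4 x min cell (19)
    tab <- table(choice[s], value[s])
    expect_true(all(tab == 19))
  }
  # all-equal cells: every subset is the full set
  ch <- rep(c(1, 1, 0, 0), each = 5)
  va <- rep(c(1, 0, 1, 0), each = 5)
  subs2 <- balanced_subsets(ch, va, n_subsets = 3, seed = 1)
  expect_true(all(vapply(subs2, function(s) identical(s, 1:20), logical(1))))
  expect_error(balanced_subsets(rep(1, 10), rep(0:1, 5), n_subsets = 2),
               "non-empty")
})

test_that("offer value categories split at the categorical border", {
  expect_equal(offer_value_category(c("50:50", "65:35", "70:30", "80:20",
                                      "90:10")),
               c(1L, 1L, 1L, 0L, 0L))
})

test_that("seven simulated subjects yield 420 trial-average samples", {
  grid <- make_grid(c(4, 4, 4), c(-6, -6, -6))
  sim <- simulate_sample_matrix(grid, data.frame(x = 0, y = 0, z = 0,
                                                 radius_mm = 5),
                                signal = "none", n_subjects = 7, seed = 3)
  expect_equal(nrow(sim$x), 420)
  expect_equal(nrow(sim$meta), 420)
  expect_equal(length(unique(sim$meta$subject)), 7)
  expect_equal(unname(table(sim$meta$subject)), rep(60L, 7),
               ignore_attr = TRUE)
})
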