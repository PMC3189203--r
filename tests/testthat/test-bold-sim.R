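test_that("double-gamma HRF has the canonical shape", {
  expect_equal(hrf(0), 0)
  tt <- seq(0, 32, by = 0.1)
  h <- hrf(tt)
  peak_t <- tt[which.max(h)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 6)
  expect_equal(max(h), 1, tolerance = 1e-6)
  # positive net response over the full window
  expect_gt(sum(h) * 0.1, 0)
})

test_that("noise-free zero-effect sessions are constant at baseline plus drift", {
  cfg <- sim_config(grid = make_grid(c(6, 6, 4), c(0, 0, 0)),
                    effect_size = list(A = c(accept = 0, reject = 0)),
                    nonspecific_response = c(A = 0),
                    drift_slope = 0, noise_sd = 0)
  sched <- build_offer_schedule(counts = c("50:50" = 2L), seed = 1)
  sched$decision <- c(1L, 0L)
  mask <- array(FALSE, cfg$grid$dim); mask[1:3] <- TRUE
  sess <- simulate_session(cfg, sched, roi_masks = list(A = mask), seed = 1)
  expect_true(all(sess$volumes == cfg$baseline))
  # with drift: every voxel follows baseline + slope * (scan - 1)
  cfg2 <- sim_config(grid = cfg$grid, effect_size = cfg$effect_size,
                     nonspecific_response = c(A = 0),
                     drift_slope = 0.05, noise_sd = 0)
  sess2 <- simulate_session(cfg2, sched, roi_masks = list(A = mask), seed = 1)
  v <- sess2$volumes[1, 1, 1, ]
  expect_equal(v, 100 + 0.05 * (seq_along(v) - 1))
})

test_that("embedded responses match the direct convolution prediction", {
  cfg <- sim_config(grid = make_grid(c(6, 6, 4), c(0, 0, 0)),
                    effect_size = list(A = c(accept = 0, reject = 1)),
                    nonspecific_response = c(A = 0),
                    drift_slope = 0, noise_sd = 0)
  sched <- build_offer_schedule(counts = c("80:20" = 2L), seed = 1)
  sched$decision <- c(0L, 1L)  # first trial rejected
  mask <- array(FALSE, cfg$grid$dim); mask[5:8] <- TRUE
  sess <- simulate_session(cfg, sched, roi_masks = list(A = mask), seed = 1)
  v <- sess$volumes[5, 1, 1, ] - 100
  # oracle: boxcar(12 s) * hrf evaluated at the post-offer scan times
  scans <- trial_scan_indices(1)
  times <- (scans - 1) * 2 - 2  # seconds after the offer onset
  oracle <- trial_regressor(times)
  expect_equal(v[scans], oracle, tolerance = 1e-8)
  expect_equal(mean(v[scans[3:5]]) - mean(v[scans[1:2]]),
               mean(oracle[3:5]) - mean(oracle[1:2]), tolerance = 1e-8)
  # the accepted trial adds nothing of its own: its window carries exactly
  # the decaying tail of the rejected trial's response
  scans2 <- trial_scan_indices(2)
  tail_times <- (scans2 - 1) * 2 - 2  # seconds after the *first* offer
  expect_equal(sess$volumes[5, 1, 1, scans2] - 100,
               trial_regressor(tail_times), tolerance = 1e-8)
})

test_that("a 60-trial session yields 660 scans and is bit-reproducible", {
  cfg <- test_sim_config()
  sched <- simulate_decisions(build_offer_schedule(seed = 1), seed = 2)
  masks <- test_roi_masks()
  a <- simulate_session(cfg, sched, roi_masks = masks, seed = 3)
  expect_equal(dim(a$volumes)[4], 660)
  b <- simulate_session(cfg, sched, roi_masks = masks, seed = 3)
  expect_identical(a$volumes, b$volumes)
  expect_false(identical(
    a$volumes, simulate_session(cfg, sched, roi_masks = masks,
                                seed = 4)$volumes))
})

test_that("noise-only sessions have the stationary AR(1) moments", {
  grid <- make_grid(c(12, 12, 8), c(0, 0, 0))
  mask <- array(TRUE, grid$dim)
  cfg <- sim_config(grid = grid,
                    effect_size = list(A = c(accept = 0, reject = 0)),
                    nonspecific_response = c(A = 0),
                    drift_slope = 0, noise_sd = 0.8, ar1_coeff = 0.4)
  sched <- build_offer_schedule(counts = c("50:50" = 10L), seed = 1)
  sched$decision <- rep(0L, 10)
  sess <- simulate_session(cfg, sched, roi_masks = list(A = mask), seed = 9)
  v <- matrix(sess$volumes, ncol = dim(sess$volumes)[4])
  v <- v - 100
  target_sd <- 0.8 / sqrt(1 - 0.4^2)
  expect_equal(mean(v), 0, tolerance = 0.01)
  expect_equal(sd(v), target_sd, tolerance = 0.02)
  # lag-1 autocorrelation close to the configured coefficient
  ac <- cor(as.numeric(v[, -1]), as.numeric(v[, -ncol(v)]))
  expect_equal(ac, 0.4, tolerance = 0.03)
})

test_that("embedded amplitude is recoverable by regression within 3 SE", {
  cfg <- sim_config(grid = make_grid(c(6, 6, 4), c(0, 0, 0)),
                    effect_size = list(A = c(accept = 0.7, reject = 0.7)),
                    nonspecific_response = c(A = 0),
                    drift_slope = 0, noise_sd = 0.5, ar1_coeff = 0)
  sched <- build_offer_schedule(counts = c("70:30" = 20L), seed = 2)
  sched$decision <- rep(c(0L, 1L), 10)
  mask <- array(FALSE, cfg$grid$dim); mask[1:72] <- TRUE
  sess <- simulate_session(cfg, sched, roi_masks = list(A = mask), seed = 21)
  n_scans <- dim(sess$volumes)[4]
  times <- (seq_len(n_scans) - 1) * 2
  reg <- rep(0, n_scans)
  for (i in seq_len(nrow(sched))) {
    rel <- times - (sched$onset_s[i] + 2)
    ok <- rel >= 0 & rel <= 32
    reg[ok] <- reg[ok] + trial_regressor(rel[ok])
  }
  roi_mean <- colMeans(matrix(sess$volumes, ncol = n_scans)[1:72, ])
  fit <- lm(roi_mean ~ reg)
  est <- coef(summary(fit))["reg", ]
  expect_lt(abs(est["Estimate"] - 0.7), 3 * est["Std. Error"])
})

test_that("stream replay preserves order, timing and content", {
  cfg <- test_sim_config()
  sched <- simulate_decisions(build_offer_schedule(
    counts = c("50:50" = 2L, "90:10" = 2L), seed = 1), seed = 2)
  sess <- simulate_session(cfg, sched, roi_masks = test_roi_masks(), seed = 3)
  st <- stream_session(sess)
  n <- dim(sess$volumes)[4]
  got <- vector("list", n)
  times <- numeric(n)
  k <- 0
  while (st$has_next()) {
    sc <- st$next_scan()
    k <- k + 1
    expect_equal(sc$scan_index, k)
    got[[k]] <- sc$volume
    times[k] <- sc$time_s
  }
  expect_equal(k, n)
  expect_null(st$next_scan())
  expect_equal(diff(times), rep(sess$tr_s, n - 1))
  rebuilt <- array(unlist(got), dim = dim(sess$volumes))
  expect_identical(rebuilt, sess$volumes)
})
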