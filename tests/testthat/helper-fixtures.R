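# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# fast ROI-noise config with the default (power-example) effect sizes
test_sim_config <- function(...) {
  sim_config(noise_scope = "roi", ...)
}

null_sim_config <- function(...) {
  sim_config(noise_scope = "roi",
             effect_size = list(AI = c(accept = 0, reject = 0),
                                LPFC = c(accept = 0, reject = 0),
                                OC = c(accept = 0, reject = 0)),
             ...)
}

test_roi_masks <- function() {
  fixture("roi_masks", function() build_roi_masks(grid = roi_sim_grid())$pooled)
}

# pilot set + initial model under the default study conditions
test_pilot <- function() {
  fixture("pilot", function() {
    p <- simulate_pilot_set(config = test_sim_config(), seed = 100)
    list(set = p, model = rvm_train(p$x, p$y))
  })
}

# one decoded session under the default conditions
test_session_log <- function() {
  fixture("session_log", function() {
    pil <- test_pilot()
    sched <- simulate_decisions(build_offer_schedule(seed = 11), seed = 311)
    sess <- simulate_session(test_sim_config(), sched,
                             roi_masks = test_roi_masks(), seed = 611)
    list(session = sess,
         log = run_online_session(sess, pil$model, pil$set))
  })
}

# small grid for whole-brain / maps unit tests
test_small_grid <- function() {
  crop_mni_grid(c(-15, 15), c(-15, 15), c(-12, 12))
}

# build a column with an exact Pearson correlation r to binary y
planted_cor_column <- function(y, r, seed) {
  set.seed(seed)
  ys <- scale(y)[, 1]
  e <- rnorm(length(y))
  e <- lm(e ~ ys)$residuals
  e <- e / sqrt(sum(e^2))
  r * ys / sqrt(sum(ys^2)) + sqrt(1 - r^2) * e
}

# separable 2D toy classification problem (10 points per class, margin 2)
separable_toy <- function(seed = 1) {
  set.seed(seed)
  x <- rbind(cbind(runif(10, -3, -1), runif(10, -3, -1)),
             cbind(runif(10, 1, 3), runif(10, 1, 3)))
  list(x = x, y = rep(c(0L, 1L), each = 10))
}
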