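#' Assemble a training set of trial features and decisions
#'
#' @param features Matrix (trials x 3 ROI t-values) or data frame.
#' @param decisions Binary decision vector (1 accept / 0 reject).
#' @param provenance "pilot" or "live" origin tag per trial (recycled).
#' @return List of class `ug_training_set` with `x`, `y`, `provenance`.
#' @export
training_set <- function(features, decisions, provenance = "pilot") {
  x <- as.matrix(features)
  y <- as.integer(decisions)
  if (nrow(x) != length(y)) stop("features and decisions lengths differ")
  if (any(!y %in% c(0L, 1L))) stop("decisions must be 0/1")
  structure(list(x = x, y = y,
                 provenance = rep_len(provenance, length(y))),
            class = "ug_training_set")
}

#' Append one trial to a training set
#'
#' The continuous-retraining rule: after the decision of trial `n-1` is
#' revealed, its feature vector and decision join the training data used to
#' retrain the classifier for trial `n`. Prior elements are unchanged and
#' keep their order.
#'
#' @param tset A `ug_training_set`.
#' @param x_new Feature vector of the revealed trial.
#' @param y_new Its decision (0/1).
#' @param provenance Origin tag, default "live".
#' @return The expanded `ug_training_set` (size + 1).
#' @export
expand_training_set <- function(tset, x_new, y_new, provenance = "live") {
  if (!y_new %in% c(0, 1)) stop("decision must be 0/1")
  tset$x <- rbind(tset$x, matrix(as.numeric(x_new), nrow = 1))
  tset$y <- c(tset$y, as.integer(y_new))
  tset$provenance <- c(tset$provenance, provenance)
  tset
}

#' @export
length.ug_training_set <- function(x) length(x$y)

#' Simulate pilot training data
#'
#' Stands in for the preliminary experiments used to initialize the online
#' classifier: full synthetic sessions for `n_subjects` pilot subjects
#' (default 2, i.e. 120 trials) are simulated and reduced to per-trial
#' feature vectors with their decisions.
#'
#' @param n_subjects Number of pilot subjects (60 trials each).
#' @param config A [sim_config()] describing the pilot acquisition.
#' @param behavior A [behavior_params()] for pilot decision behavior.
#' @param seed Integer seed; each pilot subject derives its own sub-seed.
#' @return A `ug_training_set` with provenance "pilot".
#' @export
simulate_pilot_set <- function(n_subjects = 2, config = sim_config(),
                               behavior = behavior_params(), seed = 100L) {
  feats <- NULL
  decs <- integer(0)
  masks <- build_roi_masks(grid = config$grid)$pooled
  for (s in seq_len(n_subjects)) {
    sched <- build_offer_schedule(seed = seed + 7 * s)
    sched <- simulate_decisions(sched, behavior, seed = seed + 7 * s + 1)
    sess <- simulate_session(config, sched, roi_masks = masks,
                             seed = seed + 7 * s + 2)
    f <- session_features(sess)
    feats <- rbind(feats, f)
    decs <- c(decs, sched$decision)
  }
  training_set(feats, decs, provenance = "pilot")
}

#' Offline feature extraction for a whole stored session
#'
#' Convenience path used for pilot data: ROI-mean series are extracted,
#' linearly detrended over the full session, and the five post-offer scans
#' of every trial are reduced to the three pooled ROI t-values.
#'
#' @param session A `bold_session`.
#' @return Matrix (trials x ROIs) of t-values.
#' @export
session_features <- function(session) {
  roi_means <- extract_roi_means(session)
  roi_means <- linear_detrend(roi_means)
  n_trials <- nrow(session$events)
  t(vapply(seq_len(n_trials), function(i) {
    idx <- trial_scan_indices(i, session$tr_s)
    compute_feature_vector(roi_means[idx, , drop = FALSE])
  }, numeric(ncol(roi_means))))
}

# ROI-mean signal per scan: scans x ROI matrix
extract_roi_means <- function(session) {
  v <- session$volumes
  n_scans <- dim(v)[4]
  dim(v) <- c(prod(dim(v)[1:3]), n_scans)
  out <- vapply(session$roi_masks,
                function(idx) colMeans(v[idx, , drop = FALSE]),
                numeric(n_scans))
  colnames(out) <- names(session$roi_masks)
  out
}

#' Run the online decoding loop over a session
#'
#' Steps through a session trial by trial as the scans arrive. For every
#' trial the five post-offer scans are collected, ROI-mean series
#' (detrended over all scans acquired so far) are reduced to the three
#' t-values, and the current classifier predicts the decision -- all
#' strictly before the response phase of that trial begins. The true decision is then revealed, appended to the
#' training set, and (unless `retrain = FALSE`) the classifier is retrained
#' on the expanded set, warm-started from the previous model.
#'
#' @param session A `bold_session` (its `events` carry the true decisions).
#' @param init_model `rvm_model` trained on `init_set`.
#' @param init_set `ug_training_set` of pilot data.
#' @param retrain Retrain after every revealed trial (default TRUE); FALSE
#'   freezes the initial model, as in the retraining-benefit comparison.
#' @param kernel_width Fixed kernel width; defaults to the initial model's.
#' @return Data frame of class `prediction_log`, one row per completed
#'   trial: `trial_index`, the three feature t-values, `posterior`
#'   (P(accept)), `prediction`, `truth`, `correct`, `predicted_at_s`,
#'   `response_onset_s`, `retrain_s`. Attribute `final_set` holds the
#'   expanded training set.
#' @export
run_online_session <- function(session, init_model, init_set,
                               retrain = TRUE, kernel_width = NULL) {
  if (is.null(kernel_width)) kernel_width <- init_model$kernel_width
  sched <- session$events
  n_trials <- nrow(sched)
  trial_len <- sum(trial_phase_durations())
  resp_onset <- sched$onset_s + trial_len - trial_phase_durations()[["payoff"]] -
    trial_phase_durations()[["response"]]
  scan_idx <- trial_scan_indices(seq_len(n_trials), session$tr_s)
  if (n_trials == 1) scan_idx <- matrix(scan_idx, nrow = 1)

  # ROI means are a per-scan local reduction, so extracting them up front
  # is identical to accumulating them scan by scan; everything downstream
  # (detrend, features, prediction) only ever reads scans up to the
  # current trial's 5th post-offer scan, preserving the online causality.
  n_scans <- dim(session$volumes)[4]
  roi_series <- extract_roi_means(session)
  model <- init_model
  tset <- init_set
  log <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    last_scan <- scan_idx[i, 5]
    seen <- min(last_scan, n_scans)
    if (seen < last_scan) {
      warning("session ended mid-trial; returning partial log (",
              i - 1L, " of ", n_trials, " trials)")
      log <- log[seq_len(i - 1L)]
      break
    }
    detr <- linear_detrend(roi_series[seq_len(seen), , drop = FALSE])
    feats <- compute_feature_vector(detr[scan_idx[i, ], , drop = FALSE])
    post <- rvm_predict(model, feats)
    pred <- posterior_to_label(post)
    predicted_at <- (last_scan - 1) * session$tr_s + session$tr_s
    truth <- sched$decision[i]
    tset <- expand_training_set(tset, feats, truth)
    rt <- NA_real_
    if (retrain) {
      t0 <- proc.time()[["elapsed"]]
      model <- rvm_train(tset$x, tset$y, kernel_width = kernel_width,
                         warm = model)
      rt <- proc.time()[["elapsed"]] - t0
    }
    log[[i]] <- data.frame(
      trial_index = i,
      t_lpfc = feats[["LPFC"]], t_ai = feats[["AI"]], t_oc = feats[["OC"]],
      posterior = post, prediction = pred, truth = truth,
      correct = as.integer(pred == truth),
      predicted_at_s = predicted_at,
      response_onset_s = resp_onset[i],
      retrain_s = rt
    )
  }
  out <- do.call(rbind, log)
  attr(out, "final_set") <- tset
  class(out) <- c("prediction_log", "data.frame")
  out
}

#' Session accuracy of a prediction log
#' @param log A `prediction_log`.
#' @return Percent correct over logged trials.
#' @export
session_accuracy <- function(log) {
  100 * mean(log$correct)
}

#' Write a prediction log as tab-separated text
#' @param log A `prediction_log`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_prediction_log <- function(log, path) {
  utils::write.table(as.data.frame(log), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
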