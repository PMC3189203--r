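#' Correlation-based voxel feature selection
#'
#' Keeps voxels whose Pearson correlation with the class labels exceeds
#' the threshold in absolute value (`|r| > 0.15` by default; the closed
#' band `[-0.15, 0.15]` is excluded). Computed on training samples only;
#' constant voxels are excluded.
#'
#' @param x Training sample matrix (samples x voxels).
#' @param y Binary training labels.
#' @param threshold Absolute-correlation cut, default 0.15.
#' @return Integer vector of selected voxel indices.
#' @export
select_features <- function(x, y, threshold = 0.15) {
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (length(unique(y)) < 2) stop("both classes required for selection")
  r <- suppressWarnings(as.numeric(stats::cor(x, as.numeric(y))))
  sel <- which(!is.na(r) & abs(r) > threshold)
  if (!length(sel))
    stop("no voxel passed feature selection; lower the threshold or ",
         "check that the samples carry signal")
  sel
}

#' Percent correct predictions
#'
#' @param predictions,truth Equal-length label vectors.
#' @return 100 * (number correct) / (total).
#' @export
correct_prediction_rate <- function(predictions, truth) {
  if (!length(truth)) stop("empty prediction set")
  if (length(predictions) != length(truth)) stop("length mismatch")
  100 * mean(predictions == truth)
}

#' Fit a linear SVM and extract its primal weight vector
#'
#' Thin wrapper around the LIBSVM implementation in \pkg{e1071} (C-SVC,
#' linear kernel, no internal rescaling). The primal weights are recovered
#' from the dual solution (`w = sum alpha_i y_i x_i`) and sign-normalized
#' so that a positive decision value predicts class 1.
#'
#' @param x Training matrix (samples x features).
#' @param y Binary labels (0/1 or two-level factor-compatible).
#' @param cost Soft-margin cost parameter C, default 1.
#' @return List of class `linear_svm`: `w` (feature weights), `b`
#'   (intercept), such that `x %*% w + b > 0` predicts class 1.
#' @export
fit_linear_svm <- function(x, y, cost = 1) {
  y <- as.integer(y)
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision value toward the class it encounters first
  # (fit$labels holds 1-based level codes); normalize so positive = class 1
  if (fit$levels[fit$labels[1]] == "0") {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, cost = cost), class = "linear_svm")
}

#' @rdname fit_linear_svm
#' @param model A `linear_svm`.
#' @param newx Matrix of samples to classify.
#' @return `predict_linear_svm`: integer 0/1 labels.
#' @export
predict_linear_svm <- function(model, newx) {
  as.integer(drop(as.matrix(newx) %*% model$w + model$b) > 0)
}

#' Leave-one-sample-out cross-validation with fold-internal selection
#'
#' For every held-out sample, voxels are selected and the linear SVM is
#' trained on the remaining samples only; the held-out sample is then
#' classified on the selected voxels. Folds whose training part contains a
#' single class are skipped with a warning and reported via the effective
#' sample size.
#'
#' @param x Sample matrix (samples x voxels).
#' @param y Binary labels.
#' @param threshold Feature-selection threshold.
#' @param cost SVM cost.
#' @return List: `accuracy` (percent over effective folds), `predictions`
#'   (NA where skipped), `n_effective`.
#' @export
loocv <- function(x, y, threshold = 0.15, cost = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      warning("fold ", i, " has a single training class; skipped")
      next
    }
    sel <- select_features(x[-i, , drop = FALSE], ytr, threshold)
    m <- fit_linear_svm(x[-i, sel, drop = FALSE], ytr, cost)
    pred[i] <- predict_linear_svm(m, x[i, sel, drop = FALSE])
  }
  eff <- which(!is.na(pred))
  list(accuracy = correct_prediction_rate(pred[eff], y[eff]),
       predictions = pred, n_effective = length(eff))
}

#' Leave-one-subject-out cross-subject classification
#'
#' Pools the trial samples of all but one subject for feature selection
#' and SVM training, then classifies every trial of the held-out subject.
#' Assumes per-subject z-scoring was applied upstream when the samples
#' were formed.
#'
#' @param x Sample matrix (samples x voxels).
#' @param y Binary labels.
#' @param subject Subject identifier per sample.
#' @param threshold,cost As in [loocv()].
#' @return Data frame: `subject`, `accuracy` (percent), `n_trials`; the
#'   pooled accuracy over all trials is attached as attribute `pooled`.
#' @export
leave_one_subject_out <- function(x, y, subject, threshold = 0.15, cost = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  subs <- unique(subject)
  if (length(subs) < 2) stop("need at least 2 subjects")
  rows <- lapply(subs, function(s) {
    test <- subject == s
    ytr <- y[!test]
    if (length(unique(y[test])) < 2)
      warning("held-out subject ", s, " has a single class")
    sel <- select_features(x[!test, , drop = FALSE], ytr, threshold)
    m <- fit_linear_svm(x[!test, sel, drop = FALSE], ytr, cost)
    pred <- predict_linear_svm(m, x[test, sel, drop = FALSE])
    data.frame(subject = s,
               accuracy = correct_prediction_rate(pred, y[test]),
               n_trials = sum(test))
  })
  out <- do.call(rbind, rows)
  attr(out, "pooled") <- sum(out$accuracy / 100 * out$n_trials) /
    sum(out$n_trials) * 100
  out
}

#' Balanced subsets over the choice-by-value label cells
#'
#' Draws subsets balanced with respect to the four label combinations
#' (accept/high, accept/low, reject/high, reject/low): each subset takes
#' `min cell count` samples from every cell without replacement, so the
#' subset size is four times the smallest cell.
#'
#' @param choice Binary choice labels (1 accept / 0 reject).
#' @param value Binary value labels (1 high / 0 low).
#' @param n_subsets Number of subsets (default 200).
#' @param seed Integer seed.
#' @return List of integer sample-index vectors.
#' @export
balanced_subsets <- function(choice, value, n_subsets = 200, seed = 1L) {
  cells <- split(seq_along(choice),
                 interaction(choice, value, drop = FALSE))
  if (length(cells) < 4 || any(lengths(cells) == 0))
    stop("all four choice x value cells must be non-empty")
  m <- min(lengths(cells))
  restore <- local_rng(seed)
  on.exit(restore())
  lapply(seq_len(n_subsets), function(k) {
    sort(unlist(lapply(cells, function(ix) {
      if (length(ix) == m) ix else ix[sample.int(length(ix), m)]
    }), use.names = FALSE))
  })
}

#' Choice versus value decodability on balanced subsets
#'
#' Trains two classifiers on identical balanced subsets of trials, once
#' labeled by the responder's choice (accept/reject) and once by offer
#' value (high = 50:50, 65:35, 70:30; low = 80:20, 90:10), and compares
#' their leave-one-out accuracies. Balancing the four label combinations
#' removes the correlation between choice and value, so each labeling is
#' decoded only from its own signal.
#'
#' @param x Sample matrix.
#' @param choice,value Binary label vectors (see [balanced_subsets()]).
#' @param n_subsets Number of balanced subsets (default 200).
#' @param seed Integer seed.
#' @param threshold,cost As in [loocv()].
#' @return List: `acc_choice`, `acc_value` (vectors over subsets),
#'   `summary` data frame with mean and SD per labeling.
#' @export
choice_vs_value_analysis <- function(x, choice, value, n_subsets = 200,
                                     seed = 1L, threshold = 0.15, cost = 1) {
  subsets <- balanced_subsets(choice, value, n_subsets, seed)
  acc_c <- numeric(n_subsets)
  acc_v <- numeric(n_subsets)
  for (k in seq_len(n_subsets)) {
    ix <- subsets[[k]]
    acc_c[k] <- loocv(x[ix, , drop = FALSE], choice[ix], threshold, cost)$accuracy
    acc_v[k] <- loocv(x[ix, , drop = FALSE], value[ix], threshold, cost)$accuracy
  }
  list(acc_choice = acc_c, acc_value = acc_v,
       summary = data.frame(
         labeling = c("choice", "value"),
         mean_accuracy = c(mean(acc_c), mean(acc_v)),
         sd_accuracy = c(stats::sd(acc_c), stats::sd(acc_v))))
}

#' Pairwise discrimination of adjacent offer types
#'
#' For each adjacent pair of split rates (50:50 vs 65:35, 65:35 vs 70:30,
#' 70:30 vs 80:20, 80:20 vs 90:10), repeatedly draws `per_class_n` trials
#' per split rate and runs a leave-one-out linear SVM discrimination.
#' Choice-related brain activity predicts a discrimination peak at the
#' 70:30 vs 80:20 pair, where behavior crosses the acceptance/rejection
#' category border.
#'
#' @param x Sample matrix.
#' @param offer Offer label per sample (e.g. "80:20").
#' @param per_class_n Trials drawn per split rate (default 42); reduced
#'   with a warning when a class has fewer samples.
#' @param n_reps Repetitions per pair (default 200).
#' @param seed Integer seed.
#' @param threshold,cost As in [loocv()].
#' @return Data frame: `pair`, `mean_accuracy`, `sd_accuracy`.
#' @export
adjacent_offer_discrimination <- function(x, offer, per_class_n = 42,
                                          n_reps = 200, seed = 1L,
                                          threshold = 0.15, cost = 1) {
  lv <- c("50:50", "65:35", "70:30", "80:20", "90:10")
  pairs <- cbind(lv[-5], lv[-1])
  counts <- table(factor(offer, levels = lv))
  if (min(counts) < per_class_n) {
    warning("reducing per_class_n to the smallest class count (",
            min(counts), ")")
    per_class_n <- min(counts)
  }
  restore <- local_rng(seed)
  on.exit(restore())
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    a <- which(offer == pairs[p, 1])
    b <- which(offer == pairs[p, 2])
    acc <- vapply(seq_len(n_reps), function(r) {
      ix <- c(a[sample.int(length(a), per_class_n)],
              b[sample.int(length(b), per_class_n)])
      yy <- as.integer(offer[ix] == pairs[p, 2])
      loocv(x[ix, , drop = FALSE], yy, threshold, cost)$accuracy
    }, numeric(1))
    data.frame(pair = paste(pairs[p, 1], "vs", pairs[p, 2]),
               mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc))
  })
  do.call(rbind, rows)
}

#' Offer value category of an offer label
#'
#' High offers are 50:50, 65:35 and 70:30; low offers are 80:20 and 90:10
#' -- split at the categorical acceptance border.
#'
#' @param offer Character vector of offer labels.
#' @return Integer vector: 1 = high, 0 = low.
#' @export
offer_value_category <- function(offer) {
  as.integer(offer %in% c("50:50", "65:35", "70:30"))
}
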