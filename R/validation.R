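#' Geometric mean of per-class accuracies
#'
#' The guessing-level summary statistic: the geometric mean
#' `sqrt(acc_accept * acc_reject)` of the class-wise accuracies. Unlike the
#' plain accuracy it is 0 for a classifier that always predicts one class,
#' so strategies that merely exploit class imbalance cannot look better
#' than chance.
#'
#' @param acc_accept,acc_reject Class-wise accuracies in `[0, 1]`.
#' @return Geometric mean in `[0, 1]`.
#' @examples
#' geometric_mean_accuracy(0.8, 0.5)  # sqrt(0.4)
#' @export
geometric_mean_accuracy <- function(acc_accept, acc_reject) {
  stopifnot(all(acc_accept >= 0 & acc_accept <= 1),
            all(acc_reject >= 0 & acc_reject <= 1))
  sqrt(acc_accept * acc_reject)
}

#' Permutation-based empirical guessing level
#'
#' Estimates the accuracy a classifier reaches on a data set when the
#' decisions carry no information: the decision vector is permuted
#' (destroying the feature-label coherence while retaining class sizes),
#' the classifier is retrained on the permuted labels, all trials are
#' classified by the retrained model, and the class-wise accuracies
#' against the actual decisions -- the same statistic reported for the
#' real experiment -- are summarized by their geometric mean. Repeating
#' this `n_perm` times yields the mean guessing level and its 2.5%/97.5%
#' quantiles. With imbalanced classes the guessing level sits above 50%
#' because a permutation of an imbalanced decision vector agrees with the
#' original above chance; this bias is exactly what the empirical estimate
#' is designed to expose.
#'
#' @param x Feature matrix (trials x features).
#' @param y Binary decision vector; both classes required.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed for the permutations.
#' @param method "resubstitution" (retrained model classifies the trials it
#'   was trained on, the literal reading of the estimation procedure) or
#'   "loocv" (leave-one-trial-out within each permutation).
#' @param trainer,predictor Classifier training/prediction functions;
#'   default the package RVM. `trainer(x, y, kernel_width)` must return a
#'   model for `predictor(model, x)` returning posteriors.
#' @param kernel_width Fixed kernel width passed to the trainer; default
#'   the median heuristic on `x`, computed once (permutations do not change
#'   the features).
#' @param prior_x,prior_y Optional label-fixed training data (e.g. the
#'   pilot set of the online classifier) included in every retraining but
#'   never permuted nor classified.
#' @return List of class `guessing_estimate`: `mean_level`, `q2_5`,
#'   `q97_5` (percent), `n_permutations`, `per_perm_levels`.
#' @export
empirical_guessing_level <- function(x, y, n_perm = 500, seed = 1L,
                                     method = c("resubstitution", "loocv"),
                                     trainer = NULL, predictor = NULL,
                                     kernel_width = NULL,
                                     prior_x = NULL, prior_y = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("single-class decision vector")
  if (is.null(trainer))
    trainer <- function(x, y, kernel_width) rvm_train(x, y, kernel_width)
  if (is.null(predictor)) predictor <- rvm_predict
  if (is.null(kernel_width)) kernel_width <- median_kernel_width(x)
  n <- length(y)
  restore <- local_rng(seed)
  on.exit(restore())
  levels_pct <- vapply(seq_len(n_perm), function(p) {
    yp <- y[sample.int(n)]
    post <- if (method == "resubstitution") {
      m <- trainer(rbind(prior_x, x), c(prior_y, yp), kernel_width)
      predictor(m, x)
    } else {
      vapply(seq_len(n), function(j) {
        m <- trainer(rbind(prior_x, x[-j, , drop = FALSE]),
                     c(prior_y, yp[-j]), kernel_width)
        predictor(m, x[j, , drop = FALSE])
      }, numeric(1))
    }
    # a posterior of exactly 0.5 is maximally uncertain: half credit,
    # so a degenerate (empty) model scores as the theoretical coin toss
    acc_a <- mean((post[y == 1] > 0.5) + 0.5 * (post[y == 1] == 0.5))
    acc_r <- mean((post[y == 0] < 0.5) + 0.5 * (post[y == 0] == 0.5))
    100 * geometric_mean_accuracy(acc_a, acc_r)
  }, numeric(1))
  structure(list(
    mean_level = mean(levels_pct),
    q2_5 = unname(stats::quantile(levels_pct, 0.025)),
    q97_5 = unname(stats::quantile(levels_pct, 0.975)),
    n_permutations = n_perm,
    per_perm_levels = levels_pct
  ), class = "guessing_estimate")
}

#' @export
print.guessing_estimate <- function(x, ...) {
  cat(sprintf(
    "Empirical guessing level: mean %.1f%% [%.1f%%, %.1f%%] (%d permutations)\n",
    x$mean_level, x$q2_5, x$q97_5, x$n_permutations))
  invisible(x)
}

#' Does an observed accuracy exceed the guessing level?
#'
#' True only when the observed accuracy lies strictly above the 97.5%
#' quantile of the permutation distribution -- the criterion for
#' concluding that the classifier learned from structure in the data
#' rather than from class frequencies.
#'
#' @param observed_accuracy Percent correct actually observed.
#' @param estimate A `guessing_estimate`.
#' @return Logical.
#' @export
exceeds_guessing <- function(observed_accuracy, estimate) {
  observed_accuracy > estimate$q97_5
}

#' Additional correct predictions due to continuous retraining
#'
#' Compares paired prediction logs (same sessions decoded with and without
#' per-trial retraining) in a sliding window over trials: for every window
#' position, the number of correct predictions of the frozen-model runs is
#' subtracted from that of the retrained runs, summed over sessions.
#'
#' @param retrained,frozen Lists of `prediction_log`s, paired by session
#'   and aligned by trial.
#' @param window Sliding window length in trials (default 6).
#' @return Data frame: `window_start`, `window_end`, `extra_correct`,
#'   `n_predictions` (window length x number of sessions).
#' @export
retraining_benefit <- function(retrained, frozen, window = 6) {
  if (length(retrained) != length(frozen)) stop("paired logs required")
  for (k in seq_along(retrained)) {
    if (nrow(retrained[[k]]) != nrow(frozen[[k]]) ||
        any(retrained[[k]]$trial_index != frozen[[k]]$trial_index))
      stop("logs of pair ", k, " are misaligned")
  }
  n_trials <- nrow(retrained[[1]])
  starts <- seq_len(n_trials - window + 1)
  extra <- vapply(starts, function(s) {
    w <- s:(s + window - 1)
    sum(vapply(seq_along(retrained), function(k) {
      sum(retrained[[k]]$correct[w]) - sum(frozen[[k]]$correct[w])
    }, numeric(1)))
  }, numeric(1))
  data.frame(window_start = starts, window_end = starts + window - 1,
             extra_correct = extra,
             n_predictions = window * length(retrained))
}

#' Binomial test of an accuracy against the theoretical 50% level
#'
#' Convenience utility only; inference in this package is based on the
#' empirical guessing level.
#'
#' @param n_correct,n_total Counts of correct and total predictions.
#' @return p-value of a one-sided exact binomial test against p = 0.5.
#' @export
binomial_vs_chance <- function(n_correct, n_total) {
  stats::binom.test(n_correct, n_total, p = 0.5,
                    alternative = "greater")$p.value
}
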