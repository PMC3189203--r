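#' Remove linear drift from time series
#'
#' Least-squares removal of intercept and slope per series; the output has
#' mean zero and is orthogonal to a linear trend.
#'
#' @param series Numeric vector, or matrix with one series per column.
#' @return Detrended series of the same shape.
#' @examples
#' linear_detrend(3 + 0.5 * (1:10))  # ~0 everywhere
#' @export
linear_detrend <- function(series) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 time points to detrend")
  tt <- seq_len(n)
  basis <- cbind(1, tt - mean(tt))
  res <- stats::lm.fit(basis, x)$residuals
  if (is.vector(series)) as.numeric(res) else res
}

#' High-pass filter via discrete cosine basis removal
#'
#' Removes slow signal fluctuations by projecting out the DCT-II basis
#' functions with frequency below the cut-off (plus the constant), the
#' standard drift model in fMRI analysis. Exact DC removal; components well
#' above the cut-off pass essentially unchanged.
#'
#' @param series Numeric vector or matrix (time in rows).
#' @param cutoff_hz Cut-off frequency, default 0.01 Hz.
#' @param tr_s Sampling interval (repetition time), seconds.
#' @return Filtered series, same shape.
#' @export
highpass <- function(series, cutoff_hz = 0.01, tr_s = 2) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (cutoff_hz >= 1 / (2 * tr_s)) stop("cutoff must be below Nyquist")
  # DCT basis k has frequency k / (2 * n * tr_s); drop all below cutoff
  k_max <- floor(2 * n * tr_s * cutoff_hz)
  if (n < k_max + 2) stop("series too short for requested cutoff")
  k <- 0:k_max
  tt <- seq_len(n) - 0.5
  basis <- cos(outer(tt, k * pi / n))
  res <- stats::lm.fit(basis, x)$residuals
  if (is.vector(series)) as.numeric(res) else res
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable Gaussian convolution of a 3D volume with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, using half-sample symmetric
#' (reflective) boundary handling, which conserves the volume total.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (default 9).
#' @param voxel_mm Voxel size in mm (default 3).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 9, voxel_mm = 3) {
  stopifnot(length(dim(volume)) == 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (sigma <= 0) return(volume)
  radius <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-radius, radius), sd = sigma)
  kern <- kern / sum(kern)
  out <- volume
  for (axis in 1:3) {
    out <- apply_along(out, axis, smooth_1d, kern = kern, radius = radius)
  }
  out
}

# convolve a vector with reflective (half-sample symmetric) padding
smooth_1d <- function(v, kern, radius) {
  n <- length(v)
  idx <- (1 - radius):(n + radius)
  m <- (idx - 1) %% (2 * n)
  pos <- ifelse(m < n, m + 1, 2 * n - m)
  ext <- v[pos]
  stats::filter(ext, kern, sides = 2)[radius + seq_len(n)]
}

# apply a length-preserving 1D function along one axis of a 3D array
apply_along <- function(a, axis, fun, ...) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- apply(m, 2, fun, ...)
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

#' Voxelwise z-scoring of a subject's time series
#'
#' Scales every voxel time series to mean 0 and (sample) standard
#' deviation 1 -- the per-subject normalization applied before pooling data
#' across subjects. Voxels with zero variance are set to all zeros and
#' reported via the `degenerate` attribute.
#'
#' @param series Matrix, time in rows, voxels in columns (or a vector).
#' @return Z-scored series with attribute `degenerate`: indices of
#'   zero-variance voxels.
#' @export
zscore_voxelwise <- function(series) {
  x <- as.matrix(series)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  flat <- which(sdv == 0 | !is.finite(sdv))
  sdv[flat] <- 1
  out <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  out[, flat] <- 0
  if (is.vector(series)) out <- as.numeric(out)
  attr(out, "degenerate") <- flat
  out
}

#' Scan indices of a trial relative to the offer
#'
#' "Scan 1" is the first volume acquired at or after the offer onset (the
#' offer appears 2 s into the 22 s trial, so with TR 2 s scan 1 is the
#' session scan at `(trial-1)*11 + 2`). Scans 1-5 cover the 10 s used for
#' prediction: scans 1-2 the baseline (first 4 s), scans 3-5 the active
#' window (seconds 6-10).
#'
#' @param trial_index 1-based trial number(s).
#' @param tr_s Repetition time (s).
#' @param n_scans How many post-offer scans to index (default 5).
#' @return Integer vector (or matrix for several trials) of session scan
#'   indices.
#' @export
trial_scan_indices <- function(trial_index, tr_s = 2, n_scans = 5L) {
  trial_len <- sum(trial_phase_durations())
  offer_delay <- trial_phase_durations()[["amount"]]
  first <- (trial_index - 1) * trial_len / tr_s +
    ceiling(offer_delay / tr_s) + 1
  idx <- outer(as.integer(first), 0:(n_scans - 1), `+`)
  if (length(trial_index) == 1) as.integer(idx) else idx
}

#' Pooled two-sample t-value of one ROI for one trial
#'
#' Compares the ROI-mean BOLD signal of the active window (post-offer scans
#' 3-5) against the baseline window (scans 1-2) with a pooled-variance
#' two-sample t statistic (3 degrees of freedom). A trial with zero pooled
#' variance yields t = 0 when the mean difference is zero and a signed cap
#' of +/- 1e6 otherwise.
#'
#' @param roi_signal Numeric length-5 vector: ROI-mean signal at post-offer
#'   scans 1..5.
#' @return The t-value (active minus baseline).
#' @examples
#' roi_t_value(c(1, 3, 4, 6, 5))  # 2.846
#' @export
roi_t_value <- function(roi_signal) {
  if (length(roi_signal) != 5) stop("exactly 5 post-offer scans required")
  base <- roi_signal[1:2]
  act <- roi_signal[3:5]
  ss <- sum((base - mean(base))^2) + sum((act - mean(act))^2)
  df <- 3
  pooled <- ss / df
  diff <- mean(act) - mean(base)
  if (pooled == 0) {
    if (diff == 0) return(0)
    warning("zero pooled variance with nonzero difference; capped t")
    return(sign(diff) * 1e6)
  }
  diff / sqrt(pooled * (1 / 2 + 1 / 3))
}

#' Per-trial feature vector of pooled ROI t-values
#'
#' One t-value per pooled region (LPFC, AI, OC) from the five post-offer
#' scans of a trial; the three values are the classifier input.
#'
#' @param trial_signals Matrix 5 x n_roi (rows = post-offer scans 1..5,
#'   columns named by ROI) of ROI-mean signal.
#' @return Named numeric vector of t-values, one per ROI column.
#' @export
compute_feature_vector <- function(trial_signals) {
  stopifnot(nrow(trial_signals) == 5)
  vapply(seq_len(ncol(trial_signals)),
         function(j) roi_t_value(trial_signals[, j]), numeric(1)) |>
    stats::setNames(colnames(trial_signals))
}

#' Trial-average volume for offline classification
#'
#' Voxelwise mean of the 2nd, 3rd and 4th scans after offer presentation --
#' the window in which the decision is internally made but the response
#' mapping is still unknown.
#'
#' @param trial_scans 4D array (x,y,z,scan) or matrix (voxel x scan) of at
#'   least 4 post-offer scans, scan 1 first.
#' @return 3D array (or vector for matrix input): the mean of scans 2-4.
#' @export
trial_average_volume <- function(trial_scans) {
  d <- dim(trial_scans)
  if (length(d) == 4) {
    if (d[4] < 4) stop("need at least 4 post-offer scans")
    out <- (trial_scans[, , , 2] + trial_scans[, , , 3] + trial_scans[, , , 4]) / 3
  } else {
    if (ncol(trial_scans) < 4) stop("need at least 4 post-offer scans")
    out <- rowMeans(trial_scans[, 2:4, drop = FALSE])
  }
  out
}
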