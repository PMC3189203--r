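#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response minus undershoot), zero at
#' t = 0 and peaking about 5 s after the driving event -- the build-up time
#' that motivates using the first 4 s after an offer as baseline and
#' seconds 6-10 as the active window. The returned curve is scaled so that
#' its maximum is 1.
#'
#' @param t Time(s) in seconds, >= 0.
#' @param peak_shape,peak_rate Shape/rate of the response gamma (mode
#'   `(shape-1)/rate` = 5 s by default).
#' @param under_shape,under_rate Shape/rate of the undershoot gamma.
#' @param under_ratio Undershoot amplitude relative to the response.
#' @return HRF amplitude(s), unit peak.
#' @examples
#' hrf(0)           # 0
#' hrf(5)           # ~1 (peak)
#' @export
hrf <- function(t, peak_shape = 6, peak_rate = 1, under_shape = 16,
                under_rate = 1, under_ratio = 1 / 6) {
  stopifnot(all(t >= 0))
  raw <- function(tt) {
    stats::dgamma(tt, shape = peak_shape, rate = peak_rate) -
      under_ratio * stats::dgamma(tt, shape = under_shape, rate = under_rate)
  }
  peak <- max(raw(seq(0, 32, by = 0.01)))
  raw(t) / peak
}

#' Configuration of a synthetic BOLD session
#'
#' Describes the voxel grid, acquisition timing, the class-dependent effect
#' amplitudes embedded in each region of interest, and the noise model.
#' Defaults encode the signal pattern that drives the decoder: anterior
#' insula (AI) and lateral prefrontal cortex (LPFC) respond more strongly
#' before a rejection, occipital cortex (OC) before an acceptance. Effect
#' amplitudes are in units of the constant baseline signal (baseline 100,
#' amplitude 1 = 1% signal change at the HRF peak).
#'
#' @param grid `vox_grid` the session lives on (default: a cropped MNI grid
#'   that contains all three default ROIs).
#' @param tr_s Repetition time in seconds (default 2).
#' @param baseline Constant baseline signal level.
#' @param effect_size Named list `roi -> c(accept, reject)` amplitudes.
#' @param nonspecific_response Named numeric: per-ROI amplitude added for
#'   every offer regardless of the upcoming decision (models e.g. general
#'   visual responses; used to emulate subject-specific shifts).
#' @param drift_slope Linear drift in signal units per scan.
#' @param noise_sd Innovation SD of the AR(1) voxel noise.
#' @param ar1_coeff AR(1) autocorrelation, |coeff| < 1.
#' @param noise_scope "global" (noise in every voxel) or "roi" (noise
#'   generated only inside the ROI masks -- statistically exact for every
#'   analysis that reads ROI signal only, and much faster on large grids).
#' @return List of class `bold_sim_config`.
#' @export
sim_config <- function(grid = NULL,
                       tr_s = 2,
                       baseline = 100,
                       effect_size = list(
                         AI   = c(accept = 0, reject = 1),
                         LPFC = c(accept = 0, reject = 1),
                         OC   = c(accept = 1, reject = 0)),
                       nonspecific_response = c(AI = 0, LPFC = 0, OC = 0),
                       drift_slope = 0.01,
                       noise_sd = 0.5,
                       ar1_coeff = 0.3,
                       noise_scope = c("global", "roi")) {
  if (is.null(grid)) grid <- roi_sim_grid()
  stopifnot(tr_s > 0, abs(ar1_coeff) < 1, noise_sd >= 0)
  structure(list(grid = grid, tr_s = tr_s, baseline = baseline,
                 effect_size = effect_size,
                 nonspecific_response = nonspecific_response,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 ar1_coeff = ar1_coeff,
                 noise_scope = match.arg(noise_scope)),
            class = "bold_sim_config")
}

#' Compact grid containing the three online ROIs
#'
#' A cropped MNI-lattice grid that covers the LPFC, AI and OC spheres used
#' by the online decoder; keeps single-session 4D arrays small.
#'
#' @return A `vox_grid`.
#' @export
roi_sim_grid <- function() {
  crop_mni_grid(c(-60, 60), c(-106, 40), c(-18, 24))
}

#' Expected single-trial BOLD regressor
#'
#' Boxcar over the offer phase convolved with the HRF, evaluated at times
#' `t` (seconds) relative to the offer onset. Computed on a 0.1 s lattice.
#'
#' @param t Times (s) relative to offer onset.
#' @param duration_s Offer-phase boxcar length (default 12 s).
#' @param ... Passed to [hrf()].
#' @return Regressor values (unit-HRF scale).
#' @export
trial_regressor <- function(t, duration_s = trial_phase_durations()[["offer"]],
                            ...) {
  dt <- 0.1
  tt <- seq(0, max(t) + dt, by = dt)
  box <- as.numeric(tt <= duration_s & tt > 0)
  h <- hrf(tt, ...)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tt)] * dt
  approx_idx <- pmin(pmax(round(t / dt) + 1, 1), length(tt))
  conv[approx_idx]
}

#' Simulate a 4D BOLD session with known embedded effects
#'
#' For every trial, a boxcar covering the offer phase is convolved with the
#' HRF and added to the voxels of each ROI with an amplitude that depends on
#' the (already simulated) decision. A linear drift and stationary AR(1)
#' Gaussian noise are added voxelwise. A 60-trial session at TR 2 s yields
#' 660 scans.
#'
#' @param config A [sim_config()].
#' @param schedule A `ug_schedule` with all decisions assigned.
#' @param roi_masks Named list of logical 3D arrays (or voxel index vectors)
#'   on `config$grid`; names must cover `names(config$effect_size)`.
#'   Defaults to pooled masks from [build_roi_masks()] on the config grid.
#' @param seed Integer seed (noise only; schedule carries its own).
#' @return List of class `bold_session`: `volumes` (4D array x,y,z,scan),
#'   `events` (the schedule), `grid`, `tr_s`, `roi_masks` (index form) and
#'   `roi_truth` (the embedded amplitudes).
#' @export
simulate_session <- function(config = sim_config(), schedule, roi_masks = NULL,
                             seed = 1L) {
  if (any(is.na(schedule$decision)))
    stop("all trials need decisions before simulation")
  grid <- config$grid
  if (is.null(roi_masks)) {
    roi_masks <- build_roi_masks(grid = grid)$pooled
  }
  masks <- lapply(roi_masks, function(m) {
    if (is.logical(m)) which(m) else as.integer(m)
  })
  nv <- n_voxels(grid)
  for (nm in names(config$effect_size)) {
    if (!nm %in% names(masks)) stop("no mask for ROI ", nm)
    if (any(masks[[nm]] > nv)) stop("ROI ", nm, " outside grid")
  }
  trial_len <- sum(trial_phase_durations())
  n_trials <- nrow(schedule)
  n_scans <- as.integer(n_trials * trial_len / config$tr_s)
  scan_times <- (seq_len(n_scans) - 1) * config$tr_s

  restore <- local_rng(seed)
  on.exit(restore())
  # AR(1) noise (stationary start), built in place
  roi_noise <- !is.null(config$noise_scope) && config$noise_scope == "roi"
  if (config$noise_sd > 0 && !roi_noise) {
    vol <- matrix(stats::rnorm(nv * n_scans, sd = config$noise_sd),
                  nrow = nv)
    rho <- config$ar1_coeff
    if (rho != 0) {
      vol[, 1] <- vol[, 1] / sqrt(1 - rho^2)
      for (s in 2:n_scans) vol[, s] <- rho * vol[, s - 1] + vol[, s]
    }
  } else {
    vol <- matrix(0, nrow = nv, ncol = n_scans)
    if (config$noise_sd > 0) {
      ridx <- sort(unique(unlist(masks, use.names = FALSE)))
      nr <- matrix(stats::rnorm(length(ridx) * n_scans,
                                sd = config$noise_sd), nrow = length(ridx))
      rho <- config$ar1_coeff
      if (rho != 0) {
        nr[, 1] <- nr[, 1] / sqrt(1 - rho^2)
        for (s in 2:n_scans) nr[, s] <- rho * nr[, s - 1] + nr[, s]
      }
      vol[ridx, ] <- nr
    }
  }
  # baseline + linear drift
  level <- config$baseline + config$drift_slope * (seq_len(n_scans) - 1)
  for (s in seq_len(n_scans)) vol[, s] <- vol[, s] + level[s]
  # class-dependent trial responses in the ROI voxels
  offer_onsets <- schedule$onset_s + trial_phase_durations()[["amount"]]
  for (i in seq_len(n_trials)) {
    rel <- scan_times - offer_onsets[i]
    live <- which(rel >= 0 & rel <= 32)
    if (!length(live)) next
    reg <- trial_regressor(rel[live])
    dec <- schedule$decision[i]
    for (nm in names(config$effect_size)) {
      ns <- if (nm %in% names(config$nonspecific_response))
        config$nonspecific_response[[nm]] else 0
      amp <- unname(config$effect_size[[nm]][if (dec == 1) "accept" else "reject"]) + ns
      if (amp == 0) next
      vol[masks[[nm]], live] <- vol[masks[[nm]], live] +
        rep(amp * reg, each = length(masks[[nm]]))
    }
  }
  dim(vol) <- c(grid$dim, n_scans)
  structure(list(volumes = vol, events = schedule, grid = grid,
                 tr_s = config$tr_s, roi_masks = masks,
                 roi_truth = config$effect_size, config = config),
            class = "bold_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay a stored session as a real-time scan stream
#'
#' Returns a closure-based iterator that yields volumes in acquisition
#' order, each tagged with its 1-based scan index and nominal acquisition
#' time `(index - 1) * tr_s`.
#'
#' @param session A `bold_session`.
#' @return List with functions `has_next()` and `next_scan()`; `next_scan`
#'   yields `list(volume, scan_index, time_s)` or `NULL` when exhausted.
#' @export
stream_session <- function(session) {
  n <- dim(session$volumes)[4]
  i <- 0L
  list(
    has_next = function() i < n,
    next_scan = function() {
      if (i >= n) return(NULL)
      i <<- i + 1L
      list(volume = session$volumes[, , , i, drop = TRUE],
           scan_index = i,
           time_s = (i - 1) * session$tr_s)
    },
    n_scans = n
  )
}
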