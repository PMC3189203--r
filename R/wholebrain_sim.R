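#' Discriminating volumes of the cross-subject classification
#'
#' Cluster centers (MNI mm) and volumes of the regions found informative
#' for accept/reject decisions in the offline whole-brain classification;
#' used as ground-truth geometry for map-recovery simulations.
#'
#' @return Data frame: `region`, `x`, `y`, `z`, `volume_mm3`.
#' @export
discriminating_volumes <- function() {
  data.frame(
    region = c("MFG", "vmPFC", "OFC right", "AI right", "LPFC left",
               "LPFC right", "VS", "pSTS left", "pSTS right", "OC",
               "Cerebellum left", "Cerebellum right"),
    x = c(4, -2, 20, 36, -45, 40, 2, -55, 54, -2, -47, 50),
    y = c(58, 32, 58, 24, 28, 32, 12, -42, -46, -90, -70, -72),
    z = c(6, -4, -8, 2, 28, 22, -4, 27, 26, 5, -35, -32),
    volume_mm3 = c(1629, 999, 783, 1278, 405, 2115, 1278, 1089, 1215,
                   4941, 1476, 1521),
    stringsAsFactors = FALSE
  )
}

#' Simulate trial-average whole-brain samples with planted signal
#'
#' Generates the sample matrix the offline analyses operate on: one
#' (already z-scored and trial-averaged) brain volume per trial, with
#' signal planted in spherical clusters and iid Gaussian voxel noise.
#' The signal covariate per trial is set by `signal`:
#' \describe{
#'   \item{"choice"}{+amplitude before rejections, -amplitude before
#'     acceptances (decision-locked code);}
#'   \item{"category"}{+/- amplitude by offer value category, i.e. a
#'     categorical code crossing the 70:30 / 80:20 border;}
#'   \item{"value"}{amplitude scaled linearly with the responder share
#'     (offer-magnitude code);}
#'   \item{"none"}{pure noise.}
#' }
#'
#' @param grid `vox_grid` for the samples.
#' @param clusters Data frame with columns `x`, `y`, `z` (center, mm) and
#'   either `radius_mm` or `volume_mm3`; one row per planted cluster.
#' @param signal Signal code, see above.
#' @param amplitude Cluster signal amplitude (z-score units at covariate
#'   +/- 1).
#' @param noise_sd Voxel noise SD (z-score units).
#' @param n_subjects Number of simulated subjects.
#' @param counts Offer composition per subject.
#' @param behavior [behavior_params()] used to draw decisions.
#' @param subject_specific If TRUE, every subject gets its own random
#'   cluster centers (same count/size): informative within subject, but
#'   with no shared cross-subject code.
#' @param seed Integer seed.
#' @return List: `x` (trials x voxels), `meta` (subject, trial_index,
#'   offer_label, choice, value), `grid`, `clusters` (with voxel counts).
#' @export
simulate_sample_matrix <- function(grid,
                                   clusters = NULL,
                                   signal = c("choice", "category", "value",
                                              "none"),
                                   amplitude = 0.6,
                                   noise_sd = 1,
                                   n_subjects = 7,
                                   counts = default_offer_counts(),
                                   behavior = behavior_params(),
                                   subject_specific = FALSE,
                                   seed = 1L) {
  signal <- match.arg(signal)
  nv <- n_voxels(grid)
  coords <- grid_coordinates(grid)
  if (is.null(clusters)) {
    clusters <- discriminating_volumes()[c(4, 10), ]  # right AI + OC
  }
  if (is.null(clusters$radius_mm)) {
    clusters$radius_mm <- (3 * clusters$volume_mm3 / (4 * pi))^(1 / 3)
  }
  cluster_voxels <- function(cl) {
    lapply(seq_len(nrow(cl)), function(i) {
      d2 <- (coords[, 1] - cl$x[i])^2 + (coords[, 2] - cl$y[i])^2 +
        (coords[, 3] - cl$z[i])^2
      which(d2 <= cl$radius_mm[i]^2)
    })
  }
  vox <- cluster_voxels(clusters)
  if (any(lengths(vox) == 0)) stop("planted cluster falls outside the grid")
  clusters$n_voxels <- lengths(vox)

  restore <- local_rng(seed)
  on.exit(restore())
  xs <- list()
  metas <- list()
  for (s in seq_len(n_subjects)) {
    sub_seed <- sample.int(2^30, 1)
    sched <- build_offer_schedule(counts, seed = sub_seed)
    sched <- simulate_decisions(sched, behavior, seed = sub_seed + 1)
    cov_t <- switch(signal,
      none = rep(0, nrow(sched)),
      choice = ifelse(sched$decision == 0, 1, -1),
      category = ifelse(offer_value_category(sched$offer_label) == 0, 1, -1),
      value = (sched$responder_share - 0.3) / 0.2)
    vox_s <- vox
    if (subject_specific) {
      cl_s <- clusters
      cl_s$x <- stats::runif(nrow(cl_s), min(coords[, 1]), max(coords[, 1]))
      cl_s$y <- stats::runif(nrow(cl_s), min(coords[, 2]), max(coords[, 2]))
      cl_s$z <- stats::runif(nrow(cl_s), min(coords[, 3]), max(coords[, 3]))
      vox_s <- cluster_voxels(cl_s)
    }
    xm <- matrix(stats::rnorm(nrow(sched) * nv, sd = noise_sd),
                 nrow = nrow(sched))
    for (ci in seq_along(vox_s)) {
      if (!length(vox_s[[ci]])) next
      xm[, vox_s[[ci]]] <- xm[, vox_s[[ci]]] + amplitude * cov_t
    }
    xs[[s]] <- xm
    metas[[s]] <- data.frame(
      subject = s, trial_index = sched$trial_index,
      offer_label = sched$offer_label, choice = sched$decision,
      value = offer_value_category(sched$offer_label))
  }
  list(x = do.call(rbind, xs), meta = do.call(rbind, metas), grid = grid,
       clusters = clusters)
}
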