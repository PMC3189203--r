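#' Back-project linear SVM weights into voxel space
#'
#' Scatters the weight vector of a linear classifier trained on selected
#' voxels back onto the full grid (unselected voxels get weight 0) and
#' scales the map to unit Euclidean length. The absolute weight of a voxel
#' then reflects its importance for the discrimination.
#'
#' @param model A `linear_svm` from [fit_linear_svm()].
#' @param selected Integer indices of the voxels the model was trained on.
#' @param grid `vox_grid` (or an integer voxel count) defining the map.
#' @return 3D array (or vector when `grid` is a count) of unit-norm
#'   weights, class `weight_map`.
#' @export
backproject_weights <- function(model, selected, grid) {
  nv <- if (inherits(grid, "vox_grid")) n_voxels(grid) else as.integer(grid)
  if (length(model$w) != length(selected))
    stop("model weights and selected index length differ")
  w <- numeric(nv)
  w[selected] <- model$w
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("zero-norm weight vector cannot be scaled")
  w <- w / nrm
  if (inherits(grid, "vox_grid")) {
    w <- array(w, grid$dim)
    attr(w, "grid") <- grid
  }
  class(w) <- c("weight_map", class(w))
  w
}

#' Permutation p-values for voxel weights
#'
#' Trains the full pipeline (feature selection + linear SVM + unit-norm
#' back-projection) on the observed labels and on `n_perm` label
#' permutations; each voxel's p-value is the add-one permutation
#' probability of an absolute weight at least as large as the observed
#' one: `p = (1 + #{perm >= obs}) / (n_perm + 1)`. Voxels never selected
#' get observed weight 0 and hence p = 1.
#'
#' @param x Sample matrix (samples x voxels).
#' @param y Binary labels.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param threshold,cost Pipeline parameters as in [loocv()].
#' @return List: `observed` (unit-norm weight vector), `p` (per-voxel
#'   p-values), `n_perm`.
#' @export
permutation_weight_pvalues <- function(x, y, n_perm = 1000, seed = 1L,
                                       threshold = 0.15, cost = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required")
  pipeline <- function(lab) {
    sel <- select_features(x, lab, threshold)
    m <- fit_linear_svm(x[, sel, drop = FALSE], lab, cost)
    backproject_weights(m, sel, ncol(x))
  }
  obs <- abs(pipeline(y))
  restore <- local_rng(seed)
  on.exit(restore())
  count_ge <- numeric(ncol(x))
  n <- length(y)
  for (p in seq_len(n_perm)) {
    wp <- tryCatch(abs(pipeline(y[sample.int(n)])),
                   error = function(e) numeric(ncol(x)))
    count_ge <- count_ge + (wp >= obs)
  }
  list(observed = as.numeric(obs),
       p = (1 + count_ge) / (n_perm + 1),
       n_perm = n_perm)
}

#' Label connected components of a binary 3D mask
#'
#' Breadth-first labeling under 6, 18 or 26 neighborhood connectivity.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[nz == 1, , drop = FALSE],
                "18" = off[nz >= 1 & nz <= 2, , drop = FALSE],
                "26" = off[nz >= 1, , drop = FALSE])
  labels <- array(0L, d)
  lab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      nb <- sweep(off, 2, as.integer(ci), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- lab
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

#' Cluster-extent filtering of a significance mask
#'
#' Keeps connected components whose volume reaches the minimum cluster
#' extent (300 mm^3, i.e. 12 voxels at 3 mm isotropic) and tabulates them:
#' center of mass in MNI mm, volume, voxel count and (when a weight map is
#' given) peak absolute weight.
#'
#' @param mask Logical 3D array of significant voxels.
#' @param grid `vox_grid` of the mask (for mm coordinates); optional --
#'   without it centers are in voxel units.
#' @param min_volume_mm3 Minimum cluster volume (default 300).
#' @param voxel_mm3 Voxel volume (default 27).
#' @param connectivity Component connectivity (default 26).
#' @param weights Optional weight array for peak values.
#' @return Data frame of class `cluster_table`: `cluster`, `x`, `y`, `z`,
#'   `n_voxels`, `volume_mm3`, `peak_weight`.
#' @export
cluster_filter <- function(mask, grid = NULL, min_volume_mm3 = 300,
                           voxel_mm3 = 27, connectivity = 26,
                           weights = NULL) {
  min_vox <- ceiling(min_volume_mm3 / voxel_mm3)
  labels <- label_components(mask, connectivity)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  rows <- list()
  k <- 0L
  for (id in ids) {
    ix <- which(labels == id)
    if (length(ix) < min_vox) next
    k <- k + 1L
    ci <- arrayInd(ix, dim(mask))
    com <- colMeans(ci)
    if (!is.null(grid)) com <- grid$origin_mm + (com - 1) * grid$voxel_mm
    rows[[k]] <- data.frame(
      cluster = k, x = com[1], y = com[2], z = com[3],
      n_voxels = length(ix), volume_mm3 = length(ix) * voxel_mm3,
      peak_weight = if (is.null(weights)) NA_real_ else max(abs(weights[ix])))
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(cluster = integer(), x = numeric(), y = numeric(),
               z = numeric(), n_voxels = integer(), volume_mm3 = numeric(),
               peak_weight = numeric())
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Recover planted discriminating volumes from a simulation
#'
#' End-to-end check of the map inference: simulates whole-brain samples
#' with clusters planted at known centers, runs feature selection + linear
#' SVM + unit-norm back-projection + permutation p-values, thresholds at
#' p < 0.05 and applies the cluster-extent filter, then matches recovered
#' clusters to the planted centers.
#'
#' @param sim Output of [simulate_sample_matrix()] (labels taken from
#'   `sim$meta$choice` unless `labels` given).
#' @param labels Optional explicit binary labels.
#' @param n_perm Permutations for the voxel p-values (default 1000).
#' @param p_threshold Per-voxel significance threshold (default 0.05).
#' @param seed Integer seed.
#' @param ... Passed to [permutation_weight_pvalues()].
#' @return List: `clusters` (recovered `cluster_table`), `planted`
#'   (truth with `recovered_distance_mm`: distance from each planted
#'   center to the nearest recovered cluster center), `spurious`
#'   (recovered clusters farther than 9 mm from every planted center),
#'   `pvals`.
#' @export
recover_planted_map <- function(sim, labels = NULL, n_perm = 1000,
                                p_threshold = 0.05, seed = 1L, ...) {
  if (is.null(labels)) labels <- sim$meta$choice
  res <- permutation_weight_pvalues(sim$x, labels, n_perm = n_perm,
                                    seed = seed, ...)
  p_arr <- array(res$p, sim$grid$dim)
  w_arr <- array(res$observed, sim$grid$dim)
  tab <- cluster_filter(p_arr < p_threshold, grid = sim$grid,
                        voxel_mm3 = sim$grid$voxel_mm^3, weights = w_arr)
  planted <- sim$clusters
  if (nrow(tab)) {
    planted$recovered_distance_mm <- vapply(seq_len(nrow(planted)),
      function(i) {
        min(sqrt((tab$x - planted$x[i])^2 + (tab$y - planted$y[i])^2 +
                   (tab$z - planted$z[i])^2))
      }, numeric(1))
    near <- vapply(seq_len(nrow(tab)), function(j) {
      min(sqrt((tab$x[j] - planted$x)^2 + (tab$y[j] - planted$y)^2 +
                 (tab$z[j] - planted$z)^2))
    }, numeric(1))
    spurious <- tab[near > 9, , drop = FALSE]
  } else {
    planted$recovered_distance_mm <- Inf
    spurious <- tab
  }
  list(clusters = tab, planted = planted, spurious = spurious,
       pvals = res$p)
}
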