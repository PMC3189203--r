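#' Regions of interest for online decoding
#'
#' Center coordinates (MNI mm) and volumes of the three regions whose
#' pooled t-values feed the online classifier: lateral prefrontal cortex
#' (LPFC, bilateral), anterior insula (AI, bilateral) and occipital cortex
#' (OC, midline).
#'
#' @return Data frame with columns `name`, `side`, `x`, `y`, `z`,
#'   `volume_mm3`.
#' @export
roi_table <- function() {
  data.frame(
    name = c("LPFC", "LPFC", "AI", "AI", "OC"),
    side = c("left", "right", "left", "right", "midline"),
    x = c(-50, 50, -38.5, 38.5, 0),
    y = c(28, 28, 20, 20, -88),
    z = c(11, 11, -1, -1, 3),
    volume_mm3 = c(3798, 3798, 2925, 2925, 15606),
    stringsAsFactors = FALSE
  )
}

#' Build voxel masks for the online ROIs
#'
#' Each ROI is realized as the `N = round(volume_mm3 / voxel volume)` grid
#' voxels nearest (Euclidean distance in mm) to its center -- a
#' volume-exact ball approximation. Homologous left/right masks are also
#' pooled into a single bilateral mask, matching the pooling applied before
#' t-value computation.
#'
#' @param rois ROI table as from [roi_table()].
#' @param grid `vox_grid` to rasterize onto (default [mni_grid()]).
#' @return List with `individual` (named `name.side` logical arrays) and
#'   `pooled` (named by ROI `name`, voxel index vectors of the left+right
#'   union).
#' @examples
#' m <- build_roi_masks(grid = roi_sim_grid())
#' lengths(m$pooled)
#' @export
build_roi_masks <- function(rois = roi_table(), grid = mni_grid()) {
  vox_mm3 <- grid$voxel_mm^3
  coords <- grid_coordinates(grid)
  lo <- grid$origin_mm - grid$voxel_mm / 2
  hi <- grid$origin_mm + (grid$dim - 1) * grid$voxel_mm + grid$voxel_mm / 2
  individual <- list()
  for (r in seq_len(nrow(rois))) {
    ctr <- as.numeric(rois[r, c("x", "y", "z")])
    if (any(ctr < lo) || any(ctr > hi))
      stop("ROI center ", rois$name[r], " (", rois$side[r], ") outside grid")
    n_vox <- round(rois$volume_mm3[r] / vox_mm3)
    d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
      (coords[, 3] - ctr[3])^2
    keep <- order(d2, seq_along(d2))[seq_len(n_vox)]  # ties: lowest index
    m <- array(FALSE, grid$dim)
    m[keep] <- TRUE
    individual[[paste(rois$name[r], rois$side[r], sep = ".")]] <- m
  }
  pooled <- lapply(split(seq_len(nrow(rois)), rois$name), function(ix) {
    acc <- array(FALSE, grid$dim)
    for (r in ix) {
      acc <- acc | individual[[paste(rois$name[r], rois$side[r], sep = ".")]]
    }
    which(acc)
  })
  list(individual = individual, pooled = pooled, grid = grid)
}
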