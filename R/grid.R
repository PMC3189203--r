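#' Voxel grid on the MNI lattice
#'
#' A grid is the geometry of a 3D volume: dimensions, the world (MNI, mm)
#' coordinate of the first voxel, and the isotropic voxel size. Voxel
#' `(i, j, k)` (1-based) sits at `origin_mm + (c(i, j, k) - 1) * voxel_mm`.
#'
#' @param dim Integer vector of length 3 (voxels per axis).
#' @param origin_mm World coordinate (mm) of voxel (1,1,1).
#' @param voxel_mm Isotropic voxel edge length in mm (default 3).
#' @return List of class `vox_grid`.
#' @export
make_grid <- function(dim, origin_mm, voxel_mm = 3) {
  stopifnot(length(dim) == 3, all(dim >= 1), length(origin_mm) == 3,
            voxel_mm > 0)
  structure(list(dim = as.integer(dim), origin_mm = as.numeric(origin_mm),
                 voxel_mm = voxel_mm),
            class = "vox_grid")
}

#' Full-brain MNI grid at 3 mm
#'
#' The standard 61 x 73 x 61 bounding box covering x in -90..90,
#' y in -126..90, z in -72..108 mm.
#'
#' @return A `vox_grid`.
#' @export
mni_grid <- function() {
  make_grid(c(61L, 73L, 61L), c(-90, -126, -72), 3)
}

#' Cropped grid aligned to the 3 mm MNI lattice
#'
#' Builds a sub-grid whose voxel centers lie on the same lattice as
#' [mni_grid()], covering at least the requested mm ranges. Useful for
#' reduced-grid simulations that must still report true MNI coordinates.
#'
#' @param xlim,ylim,zlim Length-2 mm ranges to cover.
#' @return A `vox_grid`.
#' @export
crop_mni_grid <- function(xlim, ylim, zlim) {
  full <- mni_grid()
  lo <- floor((c(xlim[1], ylim[1], zlim[1]) - full$origin_mm) / full$voxel_mm)
  hi <- ceiling((c(xlim[2], ylim[2], zlim[2]) - full$origin_mm) / full$voxel_mm)
  lo <- pmax(lo, 0)
  hi <- pmin(hi, full$dim - 1L)
  make_grid(hi - lo + 1L, full$origin_mm + lo * full$voxel_mm, full$voxel_mm)
}

#' Voxel-center world coordinates
#'
#' @param grid A `vox_grid`.
#' @return An `prod(grid$dim) x 3` matrix of mm coordinates in array
#'   (column-major) voxel order.
#' @export
grid_coordinates <- function(grid) {
  idx <- as.matrix(expand.grid(seq_len(grid$dim[1]), seq_len(grid$dim[2]),
                               seq_len(grid$dim[3])))
  sweep((idx - 1) * grid$voxel_mm, 2, grid$origin_mm, `+`)
}

#' Affine matrix of a grid (voxel index 0-based -> mm)
#' @param grid A `vox_grid`.
#' @return 4 x 4 affine.
#' @export
grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$voxel_mm, 3), 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

n_voxels <- function(grid) prod(grid$dim)
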