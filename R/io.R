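#' Write a simulated session to disk
#'
#' Volumes go to a NIfTI-1 file with a 3 mm isotropic MNI-oriented affine,
#' events to a tab-separated table, and the remaining metadata (grid,
#' repetition time, embedded ROI truth) to a JSON sidecar.
#'
#' @param session A `bold_session`.
#' @param dir Output directory (created if missing).
#' @param name Base name for the three files.
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir, name = "session") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img <- RNifti::asNifti(session$volumes)
  aff <- grid_affine(session$grid)
  RNifti::qform(img) <- structure(aff, code = 4L)  # MNI space
  RNifti::pixdim(img) <- c(rep(session$grid$voxel_mm, 3), session$tr_s)
  RNifti::writeNifti(img, file.path(dir, paste0(name, "_bold.nii.gz")))
  write_events(session$events, file.path(dir, paste0(name, "_events.tsv")))
  sidecar <- list(
    grid = list(dim = session$grid$dim, origin_mm = session$grid$origin_mm,
                voxel_mm = session$grid$voxel_mm),
    tr_s = session$tr_s,
    roi_truth = session$roi_truth,
    roi_masks = session$roi_masks
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @param name Base name used when writing.
#' @return A `bold_session`. Stops if the NIfTI affine does not match the
#'   sidecar grid.
#' @export
read_session <- function(dir, name = "session") {
  img <- RNifti::readNifti(file.path(dir, paste0(name, "_bold.nii.gz")))
  sidecar <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                                 simplifyVector = TRUE)
  grid <- make_grid(sidecar$grid$dim, sidecar$grid$origin_mm,
                    sidecar$grid$voxel_mm)
  aff <- RNifti::xform(img)
  if (max(abs(aff - grid_affine(grid))) > 1e-4)
    stop("NIfTI affine does not match the sidecar grid")
  events <- read_events(file.path(dir, paste0(name, "_events.tsv")))
  masks <- lapply(sidecar$roi_masks, as.integer)
  structure(list(volumes = unclass(img)[, , , , drop = FALSE],
                 events = events, grid = grid, tr_s = sidecar$tr_s,
                 roi_masks = masks, roi_truth = sidecar$roi_truth,
                 config = NULL),
            class = "bold_session")
}

#' Write ROI masks as NIfTI volumes
#'
#' One binary NIfTI per individual mask plus one per pooled bilateral
#' mask.
#'
#' @param masks Output of [build_roi_masks()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_roi_masks <- function(masks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aff <- grid_affine(masks$grid)
  wr <- function(arr, file) {
    img <- RNifti::asNifti(array(as.integer(arr), dim(arr)))
    RNifti::qform(img) <- structure(aff, code = 4L)
    RNifti::writeNifti(img, file)
  }
  for (nm in names(masks$individual)) {
    wr(masks$individual[[nm]], file.path(dir, paste0("roi_", nm, ".nii.gz")))
  }
  for (nm in names(masks$pooled)) {
    arr <- array(FALSE, masks$grid$dim)
    arr[masks$pooled[[nm]]] <- TRUE
    wr(arr, file.path(dir, paste0("roi_", nm, "_pooled.nii.gz")))
  }
  invisible(dir)
}

#' Serialize / restore an RVM model as JSON
#'
#' The snapshot holds the kernel type and width, relevance vectors,
#' weights, bias and hyperparameters -- enough to reproduce predictions
#' exactly.
#'
#' @param model An `rvm_model`.
#' @param path JSON file path.
#' @return `write_rvm_model`: `path` invisibly; `read_rvm_model`: the
#'   restored `rvm_model` (prediction-equivalent; training-state vectors
#'   for warm starts are preserved).
#' @export
write_rvm_model <- function(model, path) {
  payload <- list(
    kernel = "rbf",
    kernel_width = model$kernel_width,
    relevance_vectors = model$relevance_vectors,
    rv_index = model$rv_index,
    weights = model$weights,
    bias = model$bias,
    alpha = model$alpha,
    alpha_full = ifelse(is.finite(model$alpha_full), model$alpha_full, -1),
    weights_full = model$weights_full,
    converged = model$converged,
    iterations = model$iterations,
    n_train = model$n_train
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rvm_model
#' @export
read_rvm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  af <- as.numeric(p$alpha_full)
  af[af < 0] <- Inf
  structure(list(
    relevance_vectors = matrix(as.numeric(p$relevance_vectors),
                               nrow = length(p$weights)),
    rv_index = as.integer(p$rv_index),
    weights = as.numeric(p$weights),
    bias = as.numeric(p$bias),
    alpha = as.numeric(p$alpha),
    alpha_full = af,
    weights_full = as.numeric(p$weights_full),
    kernel_width = as.numeric(p$kernel_width),
    converged = isTRUE(p$converged),
    iterations = as.integer(p$iterations),
    n_train = as.integer(p$n_train)
  ), class = "rvm_model")
}
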