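MASK_LABELS <- c(background = 0L, thrombus = 1L, stent_tip = 2L)

#' Spatio-temporal segmentation mask
#'
#' Integer label volume `[row, col, t]` aligned to a (cropped) frame series:
#' 0 background, 1 thrombus, 2 stent-tip marker.
#'
#' @param voxels Integer array `H x W x T` with values in `{0, 1, 2}` (a
#'   matrix or logical array is accepted and coerced).
#' @param calibration A [calibration()] object.
#' @return An object of class `"segmentation_mask"`.
#' @export
segmentation_mask <- function(voxels, calibration) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("voxels must be an H x W x T array", call. = FALSE)
  }
  storage.mode(voxels) <- "integer"
  if (anyNA(voxels) || !all(voxels %in% MASK_LABELS)) {
    stop("mask labels must be 0 (background), 1 (thrombus) or 2 (stent tip)",
         call. = FALSE)
  }
  stopifnot(inherits(calibration, "calibration"))
  structure(list(voxels = voxels, calibration = calibration),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("segmentation_mask: %d x %d px, %d frames; %d thrombus, %d stent-tip voxels\n",
              d[1L], d[2L], d[3L], sum(x$voxels == 1L), sum(x$voxels == 2L)))
  invisible(x)
}

#' @export
dim.segmentation_mask <- function(x) dim(x$voxels)

#' Read and write label masks as NIfTI-1
#'
#' Masks are stored as NIfTI-1 integer volumes with the frame (time) axis as
#' the third dimension. Pixel spacing goes into the first two voxel-dimension
#' fields (mm) and the frame period `1/frame_rate` (seconds) into the third,
#' so the calibration round-trips with the voxels. NIfTI-1 keeps voxel
#' dimensions as 32-bit floats; spacings are recovered at that precision.
#'
#' @param mask A [segmentation_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `save_mask()` returns `path` invisibly; `load_mask()` returns a
#'   [segmentation_mask()].
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  cal <- mask$calibration
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- c(cal$pixel_spacing_row, cal$pixel_spacing_col,
                           1 / cal$frame_rate)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(dim(img)) != 3L || length(pd) < 3L || any(pd[1:3] <= 0)) {
    stop("expected a 3-dimensional NIfTI label mask with positive voxel dimensions",
         call. = FALSE)
  }
  segmentation_mask(array(as.integer(img), dim = dim(img)),
                    calibration(pd[1L], pd[2L], 1 / pd[3L]))
}

#' Programmatic mask editing
#'
#' Stand-in for the physician's manual correction pass: applies an ordered
#' list of voxel-set edits. Each edit is a list with `action` (`"add"` or
#' `"remove"`), `label` (1 or 2), and `voxels`, an `n x 3` matrix of
#' `(row, col, t)` indices. `"add"` sets the label at those voxels;
#' `"remove"` resets them to background only where they currently carry
#' `label`.
#'
#' @param mask A [segmentation_mask()].
#' @param edits List of edit records, applied in order.
#' @return The edited [segmentation_mask()].
#' @export
edit_mask <- function(mask, edits) {
  stopifnot(inherits(mask, "segmentation_mask"))
  vox <- mask$voxels
  d <- dim(vox)
  for (e in edits) {
    if (!is.list(e) || is.null(e$action) || is.null(e$voxels)) {
      stop("each edit needs fields 'action' and 'voxels'", call. = FALSE)
    }
    label <- as.integer(if (is.null(e$label)) 1L else e$label)
    if (!label %in% c(1L, 2L)) stop("edit label must be 1 or 2", call. = FALSE)
    idx <- matrix(as.integer(e$voxels), ncol = 3L)
    if (nrow(idx) == 0L) next
    if (any(idx < 1L) || any(idx[, 1L] > d[1L]) || any(idx[, 2L] > d[2L]) ||
        any(idx[, 3L] > d[3L])) {
      stop("edit voxels out of mask bounds", call. = FALSE)
    }
    if (e$action == "add") {
      vox[idx] <- label
    } else if (e$action == "remove") {
      cur <- vox[idx]
      vox[idx[cur == label, , drop = FALSE]] <- 0L
    } else {
      stop("edit action must be 'add' or 'remove'", call. = FALSE)
    }
  }
  segmentation_mask(vox, mask$calibration)
}
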