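#' Calibrated grayscale frame series
#'
#' The raw observable of a retrieval: an ordered stack of T grayscale frames
#' of identical size, plus the physical calibration. Frames are stored as a
#' numeric array `[row, col, t]`. Rows are the vessel (Y) axis with
#' increasing row index pointing in the distal direction; columns are X.
#'
#' @param frames Numeric array `H x W x T` (a matrix is promoted to T = 1),
#'   or a list of equally sized matrices.
#' @param calibration A [calibration()] object.
#' @return An object of class `"frame_series"` with elements `frames` and
#'   `calibration`.
#' @export
frame_series <- function(frames, calibration) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L || length(dims[[1L]]) != 2L) {
      stop("all frames must be matrices of identical size", call. = FALSE)
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be an H x W x T array", call. = FALSE)
  }
  if (dim(frames)[3L] < 1L) stop("a series needs at least one frame", call. = FALSE)
  if (!all(is.finite(frames))) stop("frame intensities must be finite", call. = FALSE)
  stopifnot(inherits(calibration, "calibration"))
  structure(list(frames = frames, calibration = calibration),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_series: %d frames of %d x %d px\n", d[3L], d[1L], d[2L]))
  print(x$calibration)
  invisible(x)
}

#' @export
dim.frame_series <- function(x) dim(x$frames)

#' Number of frames in a series or mask
#' @param x A `frame_series`, `normalized_series` or `segmentation_mask`.
#' @return Integer frame count T.
#' @export
n_frames <- function(x) {
  dim(if (!is.null(x$frames)) x$frames else x$voxels)[3L]
}

#' Rectangular region of interest
#'
#' A pixel-index box `[r0, r1] x [c0, c1]` (1-based, inclusive) drawn by the
#' operator around the vessel model; because the model is stationary, one box
#' is valid for all frames.
#'
#' @param r0,r1 First and last row (inclusive).
#' @param c0,c1 First and last column (inclusive).
#' @return An object of class `"roi_box"`.
#' @export
roi_box <- function(r0, r1, c0, c1) {
  v <- c(r0, r1, c0, c1)
  if (any(v != as.integer(v)) || any(v < 1L)) {
    stop("roi indices must be positive integers", call. = FALSE)
  }
  if (r1 < r0 || c1 < c0) stop("empty roi: need r0 <= r1 and c0 <= c1", call. = FALSE)
  structure(list(r0 = as.integer(r0), r1 = as.integer(r1),
                 c0 = as.integer(c0), c1 = as.integer(c1)),
            class = "roi_box")
}

roi_dims <- function(roi) c(roi$r1 - roi$r0 + 1L, roi$c1 - roi$c0 + 1L)

#' Crop a frame series to a region of interest
#'
#' Restricts every frame to the operator-chosen box; calibration is
#' unchanged. In the study workflow this removes roughly 80-90% of the
#' pixels before any further processing.
#'
#' @param series A [frame_series()].
#' @param roi A [roi_box()] inside the frame bounds.
#' @return A cropped `frame_series`.
#' @export
crop_series <- function(series, roi) {
  stopifnot(inherits(series, "frame_series"), inherits(roi, "roi_box"))
  d <- dim(series$frames)
  if (roi$r1 > d[1L] || roi$c1 > d[2L]) {
    stop(sprintf("roi [%d,%d]x[%d,%d] exceeds frame bounds %d x %d",
                 roi$r0, roi$r1, roi$c0, roi$c1, d[1L], d[2L]), call. = FALSE)
  }
  frame_series(series$frames[roi$r0:roi$r1, roi$c0:roi$c1, , drop = FALSE],
               series$calibration)
}

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "calibration.json")
  else paste0(sub("\\.(tiff?|png)$", "", path, ignore.case = TRUE), ".json")
}

read_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pixel_spacing_row_mm", "pixel_spacing_col_mm", "frame_rate_fps")
  if (!all(need %in% names(meta))) {
    stop("calibration sidecar must contain ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  calibration(meta$pixel_spacing_row_mm, meta$pixel_spacing_col_mm,
              meta$frame_rate_fps)
}

write_sidecar <- function(cal, path) {
  jsonlite::write_json(
    list(pixel_spacing_row_mm = cal$pixel_spacing_row,
         pixel_spacing_col_mm = cal$pixel_spacing_col,
         frame_rate_fps = cal$frame_rate),
    path, auto_unbox = TRUE, digits = NA)
}

#' Load a calibrated frame series
#'
#' Reads a multi-page TIFF stack, or a directory of TIFF/PNG frames in
#' lexicographic (acquisition) order, together with a JSON calibration
#' sidecar (`<stem>.json` next to a stack file, or `calibration.json` inside
#' a frame directory) holding `pixel_spacing_row_mm`, `pixel_spacing_col_mm`
#' and `frame_rate_fps`. A `fallback_calibration` is used when no sidecar is
#' present.
#'
#' @param path A TIFF stack file or a directory of single-frame images.
#' @param fallback_calibration Optional [calibration()] used when no sidecar
#'   exists.
#' @return A [frame_series()].
#' @export
load_series <- function(path, fallback_calibration = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tiff?|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no TIFF/PNG frames in ", path, call. = FALSE)
    frames <- lapply(sort(files), read_frame_file)
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      frames <- list(read_frame_file(path))
    } else {
      raw <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
      if (is.matrix(raw)) raw <- list(raw)
      frames <- lapply(raw, drop_channels)
    }
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) {
    stop("inconsistent frame shapes across the stack", call. = FALSE)
  }
  sc <- sidecar_path(path)
  cal <- if (file.exists(sc)) read_sidecar(sc) else fallback_calibration
  if (is.null(cal)) {
    stop("no calibration: neither sidecar ", sc,
         " nor fallback_calibration given", call. = FALSE)
  }
  frame_series(frames, cal)
}

read_frame_file <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
         else tiff::readTIFF(f)
  drop_channels(img)
}

drop_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale content only
  img
}

#' Write a frame series as a TIFF stack with calibration sidecar
#'
#' Intensities are rescaled to `[0, 1]` for storage (TIFF grayscale);
#' the affine rescaling is recorded nowhere because downstream processing is
#' invariant to it (median-baseline subtraction and drag-derived thresholds
#' both operate on the stored scale).
#'
#' @param series A [frame_series()].
#' @param path Output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
save_series <- function(series, path) {
  stopifnot(inherits(series, "frame_series"))
  f <- series$frames
  rng <- range(f)
  if (rng[2L] > rng[1L]) f <- (f - rng[1L]) / (rng[2L] - rng[1L])
  else f <- array(0, dim(f))
  pages <- lapply(seq_len(dim(f)[3L]), function(t) f[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  write_sidecar(series$calibration, sidecar_path(path))
  invisible(path)
}
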