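#' Seed path traced on one frame
#'
#' The programmatic equivalent of the operator's click-and-drag on a single
#' frame: an ordered set of pixel coordinates, all on the same frame. The
#' intensities touched along the path define the threshold interval and the
#' touched pixels seed the flood fill.
#'
#' @param t Frame index (1-based).
#' @param coords `n x 2` integer matrix of `(row, col)` pixel coordinates.
#' @return An object of class `"seed_path"`.
#' @export
seed_path <- function(t, coords) {
  coords <- matrix(as.integer(coords), ncol = 2L)
  if (nrow(coords) == 0L) stop("seed path must be non-empty", call. = FALSE)
  t <- as.integer(t)
  if (length(t) != 1L || t < 1L) stop("t must be a single positive frame index",
                                      call. = FALSE)
  structure(list(t = t, coords = coords), class = "seed_path")
}

check_path_bounds <- function(path, d) {
  if (path$t > d[3L] || any(path$coords < 1L) ||
      any(path$coords[, 1L] > d[1L]) || any(path$coords[, 2L] > d[2L])) {
    stop("seed path leaves the frame bounds", call. = FALSE)
  }
}

#' Threshold interval from a drag path
#'
#' The inclusive `[lo, hi]` interval spanned by the normalized intensities
#' under the dragged path: `lo` is their minimum, `hi` their maximum.
#'
#' @param ns A [normalize_series()] result.
#' @param path A [seed_path()] on a frame of `ns`.
#' @return A list with class `"threshold_interval"` and elements `lo`, `hi`.
#' @export
interval_from_path <- function(ns, path) {
  stopifnot(inherits(ns, "normalized_series"), inherits(path, "seed_path"))
  check_path_bounds(path, dim(ns$frames))
  vals <- ns$frames[cbind(path$coords, path$t)]
  threshold_interval(min(vals), max(vals))
}

#' @rdname interval_from_path
#' @param lo,hi Inclusive bounds on normalized intensity.
#' @export
threshold_interval <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    stop("threshold interval needs finite lo <= hi", call. = FALSE)
  }
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "threshold_interval")
}

in_interval <- function(frame, interval) {
  frame >= interval$lo & frame <= interval$hi
}

# One dilation step of `reach` restricted to `within`, by 4- or 8-connectivity.
# Matrix-shift formulation: no per-pixel loops.
dilate_step <- function(reach, within, connectivity) {
  d <- dim(reach)
  out <- reach
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  for (s in shifts) {
    sh <- matrix(FALSE, d[1L], d[2L])
    r_src <- max(1L, 1L - s[1L]):min(d[1L], d[1L] - s[1L])
    c_src <- max(1L, 1L - s[2L]):min(d[2L], d[2L] - s[2L])
    sh[r_src + s[1L], c_src + s[2L]] <- reach[r_src, c_src]
    out <- out | sh
  }
  out & within
}

#' Threshold-bounded 2D flood fill
#'
#' Returns the union of connected components (4- or 8-connectivity) of the
#' in-interval pixel set that contain at least one in-interval seed. Seeds
#' whose own intensity falls outside the interval contribute nothing.
#'
#' @param frame Numeric matrix (one normalized frame).
#' @param seeds `n x 2` integer matrix of `(row, col)` seed pixels.
#' @param interval A [threshold_interval()].
#' @param connectivity 4 or 8 (default 8).
#' @return Logical matrix of the same size as `frame`.
#' @export
flood_fill_2d <- function(frame, seeds, interval, connectivity = 8L) {
  stopifnot(is.matrix(frame), inherits(interval, "threshold_interval"))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  connectivity <- as.integer(connectivity)
  seeds <- matrix(as.integer(seeds), ncol = 2L)
  if (nrow(seeds) == 0L) stop("seed set must be non-empty", call. = FALSE)
  d <- dim(frame)
  if (any(seeds < 1L) || any(seeds[, 1L] > d[1L]) || any(seeds[, 2L] > d[2L])) {
    stop("seeds outside frame bounds", call. = FALSE)
  }
  within <- in_interval(frame, interval)
  reach <- matrix(FALSE, d[1L], d[2L])
  reach[seeds] <- TRUE
  reach <- reach & within
  repeat {
    grown <- dilate_step(reach, within, connectivity)
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

touches_border <- function(mask2d) {
  d <- dim(mask2d)
  b <- matrix(FALSE, d[1L], d[2L])
  b[c(1L, d[1L]), ] <- TRUE
  b[, c(1L, d[2L])] <- TRUE
  b & mask2d
}

# TRUE when every retained pixel lies on the image border ("ROI left the frame").
all_on_border <- function(mask2d) {
  n <- sum(mask2d)
  n > 0L && sum(touches_border(mask2d)) == n
}

#' Temporal propagation of a single-frame segmentation
#'
#' Starting from a 2D mask on frame `t0`, propagates forward and backward in
#' time. For each transition the seed set on the new frame is the previous
#' frame's mask filtered by the threshold interval on the new frame's
#' intensities; [flood_fill_2d()] is then run with those seeds. Propagation
#' in a direction stops when the new mask is empty, or once every retained
#' pixel touches the image border (the structure has left the field of
#' view); frames beyond a stop stay empty.
#'
#' @param ns A [normalize_series()] result.
#' @param t0 Frame index of the initial mask.
#' @param mask0 Logical matrix: the segmentation on frame `t0`.
#' @param interval A [threshold_interval()], held fixed for all frames.
#' @param connectivity 4 or 8 (default 8).
#' @return A logical array `H x W x T`.
#' @export
propagate_temporal <- function(ns, t0, mask0, interval, connectivity = 8L) {
  stopifnot(inherits(ns, "normalized_series"))
  d <- dim(ns$frames)
  if (t0 < 1L || t0 > d[3L]) stop("t0 outside the series", call. = FALSE)
  if (!is.matrix(mask0) || !identical(dim(mask0), d[1:2])) {
    stop("mask0 must match the frame size", call. = FALSE)
  }
  if (!any(mask0)) stop("mask0 must be non-empty", call. = FALSE)
  out <- array(FALSE, dim = d)
  out[, , t0] <- mask0
  for (step in c(1L, -1L)) {
    prev <- mask0
    t <- t0 + step
    while (t >= 1L && t <= d[3L]) {
      frame <- ns$frames[, , t]
      seed_mask <- prev & in_interval(frame, interval)
      if (!any(seed_mask)) break
      new_mask <- flood_fill_2d(frame, which(seed_mask, arr.ind = TRUE),
                                interval, connectivity)
      if (!any(new_mask)) break
      out[, , t] <- new_mask
      if (all_on_border(new_mask)) break
      prev <- new_mask
      t <- t + step
    }
  }
  out
}

#' Segment one retrieval from two drag paths
#'
#' Runs the drag-threshold-flood-fill-propagate workflow once for the
#' radiolucent thrombus and once for the radiopaque stent-tip marker, and
#' combines the two propagated masks into a label volume (1 = thrombus,
#' 2 = stent tip). Where the masks overlap the stent-tip label wins: the
#' radiopaque marker occludes the clot.
#'
#' @param ns A [normalize_series()] result.
#' @param thrombus_path,stent_path [seed_path()] objects on frames of `ns`.
#' @param connectivity 4 or 8 (default 8).
#' @return A [segmentation_mask()].
#' @export
segment_retrieval <- function(ns, thrombus_path, stent_path = NULL,
                              connectivity = 8L) {
  stopifnot(inherits(ns, "normalized_series"))
  thr <- propagate_path(ns, thrombus_path, connectivity)
  if (!any(thr[, , thrombus_path$t])) {
    stop("thrombus mask empty at the seed frame; check the drag path",
         call. = FALSE)
  }
  vox <- array(0L, dim = dim(ns$frames))
  vox[thr] <- 1L
  if (!is.null(stent_path)) {
    st <- propagate_path(ns, stent_path, connectivity)
    if (!any(st)) {
      warning("stent-tip mask is empty; path may lie on background intensity",
              call. = FALSE)
    }
    vox[st] <- 2L
  }
  segmentation_mask(vox, ns$calibration)
}

# Drag path -> interval -> seed-frame flood fill -> temporal propagation.
propagate_path <- function(ns, path, connectivity) {
  stopifnot(inherits(path, "seed_path"))
  check_path_bounds(path, dim(ns$frames))
  interval <- interval_from_path(ns, path)
  frame0 <- ns$frames[, , path$t]
  mask0 <- flood_fill_2d(frame0, path$coords, interval, connectivity)
  if (!any(mask0)) {
    return(array(FALSE, dim = dim(ns$frames)))
  }
  propagate_temporal(ns, path$t, mask0, interval, connectivity)
}
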