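#' Temporal median baseline
#'
#' Per-pixel median over all frames. Because the vessel model is stationary,
#' any structure present in at least half of the frames survives into the
#' median while moving content (thrombus, devices) is suppressed, leaving
#' the blank model as a subtractable background. For even T the median is
#' the mean of the two central order statistics.
#'
#' @param series A [frame_series()].
#' @return A numeric `H x W` matrix.
#' @export
median_baseline <- function(series) {
  stopifnot(inherits(series, "frame_series"))
  d <- dim(series$frames)
  if (d[3L] == 1L) return(series$frames[, , 1L])
  apply(series$frames, c(1L, 2L), stats::median)
}

#' Baseline-normalized frame series
#'
#' Subtracts the temporal median baseline from every frame. Static
#' structures map to (near) zero; a moving radiolucent thrombus becomes
#' positive where it displaces contrast and the radiopaque stent-tip marker
#' becomes negative. Values stay signed: the two targets have opposite
#' polarity and the drag-derived threshold interval operates on signed
#' intensities. A pixel occupied by moving content in at least half of the
#' frames leaks into the baseline and is no longer zeroed - the documented
#' failure mode of median normalization.
#'
#' @param series A [frame_series()], typically already cropped.
#' @param roi Optional [roi_box()]; when given, [crop_series()] is applied
#'   first and recorded as `source_roi`.
#' @return An object of class `"normalized_series"` with elements `frames`
#'   (signed array `H x W x T`), `calibration`, `baseline` and `source_roi`.
#' @export
normalize_series <- function(series, roi = NULL) {
  stopifnot(inherits(series, "frame_series"))
  if (!is.null(roi)) series <- crop_series(series, roi)
  base <- median_baseline(series)
  norm <- sweep(series$frames, c(1L, 2L), base, "-")
  structure(list(frames = norm, calibration = series$calibration,
                 baseline = base, source_roi = roi),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("normalized_series: %d frames of %d x %d px, intensity range [%.3g, %.3g]\n",
              d[3L], d[1L], d[2L], min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.normalized_series <- function(x) dim(x$frames)
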