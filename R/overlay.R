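mask_frames_logical <- function(mask, label = 1L) {
  lapply(seq_len(dim(mask$voxels)[3L]),
         function(t) mask$voxels[, , t] == label)
}

shift_mask <- function(m, dr, dc) {
  d <- dim(m)
  out <- matrix(FALSE, d[1L], d[2L])
  r_src <- max(1L, 1L - dr):min(d[1L], d[1L] - dr)
  c_src <- max(1L, 1L - dc):min(d[2L], d[2L] - dc)
  if (r_src[1L] > r_src[length(r_src)] || c_src[1L] > c_src[length(c_src)]) {
    return(out)
  }
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

#' Overlap-maximizing frame alignment
#'
#' Integer `(dr, dc)` shift per frame for the temporal overlay. The first
#' nonempty frame is the reference (shift 0). Each later frame is first
#' centered on the previous aligned frame's GCOG, then refined by a greedy
#' search within `radius` pixels of that initialization, maximizing pixel
#' overlap with the previous aligned thrombus mask. Ties are broken by the
#' smallest total shift `|dr| + |dc|`, then lexicographically.
#'
#' @param mask A [segmentation_mask()] (label 1 is aligned).
#' @param radius Search radius in pixels around the GCOG initialization.
#' @return Integer matrix `T x 2` of row/col shifts (`NA` for empty frames).
#' @export
align_frames <- function(mask, radius = 5L) {
  stopifnot(inherits(mask, "segmentation_mask"))
  frames <- mask_frames_logical(mask)
  TT <- length(frames)
  nonempty <- vapply(frames, any, logical(1))
  if (!any(nonempty)) stop("all frames are empty", call. = FALSE)
  shifts <- matrix(NA_integer_, TT, 2L,
                   dimnames = list(NULL, c("dr", "dc")))
  gcog <- function(m) {
    px <- which(m, arr.ind = TRUE)
    c(mean(px[, 1L]), mean(px[, 2L]))
  }
  first <- which(nonempty)[1L]
  shifts[first, ] <- c(0L, 0L)
  prev_aligned <- frames[[first]]
  for (t in which(nonempty)) {
    if (t <= first) next
    base <- round(gcog(prev_aligned) - gcog(frames[[t]]))
    best <- NULL
    for (dr in (base[1L] - radius):(base[1L] + radius)) {
      for (dc in (base[2L] - radius):(base[2L] + radius)) {
        ov <- sum(shift_mask(frames[[t]], dr, dc) & prev_aligned)
        key <- c(ov, -(abs(dr) + abs(dc)), -dr, -dc)
        if (is.null(best) || lex_greater(key, best$key)) {
          best <- list(key = key, dr = dr, dc = dc)
        }
      }
    }
    shifts[t, ] <- c(best$dr, best$dc)
    prev_aligned <- shift_mask(frames[[t]], best$dr, best$dc)
  }
  shifts
}

lex_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] != b[i]) return(a[i] > b[i])
  }
  FALSE
}

#' Colored temporal overlay
#'
#' Stacks the aligned per-frame thrombus masks into one image summarizing a
#' whole retrieval: the hue of each painted pixel interpolates from red
#' (start of the retrieval) to green (end) according to the mean time index
#' of its contributions, and its brightness scales linearly from 50% (a
#' pixel present at a single time point) to 100% (the maximum observed
#' overlap). Unpainted pixels stay black.
#'
#' @param mask A [segmentation_mask()].
#' @param shifts Output of [align_frames()]; computed when `NULL`.
#' @param outline_only Paint only the contour pixels of each frame instead
#'   of the filled mask.
#' @param radius Passed to [align_frames()] when `shifts` is `NULL`.
#' @return Object of class `"overlay_image"`: list with `rgb`
#'   (`H x W x 3` in `[0, 1]`), `overlap` (counts) and `mean_time`.
#' @export
render_overlay <- function(mask, shifts = NULL, outline_only = FALSE,
                           radius = 5L) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (is.null(shifts)) shifts <- align_frames(mask, radius)
  frames <- mask_frames_logical(mask)
  TT <- length(frames)
  d <- dim(frames[[1L]])
  count <- matrix(0L, d[1L], d[2L])
  tsum <- matrix(0, d[1L], d[2L])
  for (t in seq_len(TT)) {
    if (is.na(shifts[t, 1L]) || !any(frames[[t]])) next
    m <- frames[[t]]
    if (outline_only) {
      o <- matrix(FALSE, d[1L], d[2L])
      o[contour_pixels(m)] <- TRUE
      m <- o
    }
    m <- shift_mask(m, shifts[t, 1L], shifts[t, 2L])
    count <- count + m
    tsum <- tsum + m * (t - 1L)
  }
  painted <- count > 0L
  mean_time <- matrix(NA_real_, d[1L], d[2L])
  mean_time[painted] <- tsum[painted] / count[painted]
  # hue 0 (red) .. 1/3 (green); brightness 0.5 .. 1 linear in overlap
  frac <- if (TT > 1L) mean_time / (TT - 1L) else mean_time * 0
  maxov <- max(count)
  val <- matrix(0, d[1L], d[2L])
  val[painted] <- if (maxov > 1L) 0.5 + 0.5 * (count[painted] - 1L) / (maxov - 1L)
                  else 1
  rgb_arr <- array(0, dim = c(d, 3L))
  if (any(painted)) {
    # full-saturation hue in [0, 1/3]: red -> yellow -> green, computed in
    # floating point (grDevices::hsv would quantize brightness to 8 bits)
    cm <- hue_ramp_rgb(frac[painted], val[painted])
    for (k in 1:3) {
      plane <- matrix(0, d[1L], d[2L])
      plane[painted] <- cm[, k]
      rgb_arr[, , k] <- plane
    }
  }
  structure(list(rgb = rgb_arr, overlap = count, mean_time = mean_time,
                 shifts = shifts),
            class = "overlay_image")
}

hue_ramp_rgb <- function(frac, value) {
  h6 <- pmin(pmax(frac, 0), 1) * 2  # time fraction -> hue*6 in [0, 2]
  r <- value * ifelse(h6 <= 1, 1, 2 - h6)
  g <- value * ifelse(h6 <= 1, h6, 1)
  cbind(r, g, b = 0)
}

#' @export
print.overlay_image <- function(x, ...) {
  cat(sprintf("overlay_image: %d x %d px, max overlap %d\n",
              nrow(x$overlap), ncol(x$overlap), max(x$overlap)))
  invisible(x)
}

#' @rdname render_overlay
#' @param overlay An `overlay_image`.
#' @param path Output PNG path.
#' @export
write_overlay_png <- function(overlay, path) {
  stopifnot(inherits(overlay, "overlay_image"))
  png::writePNG(overlay$rgb, path)
  invisible(path)
}
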