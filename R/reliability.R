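as_binary_volume <- function(x, label = 1L) {
  if (inherits(x, "segmentation_mask")) return(x$voxels == label)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  x != 0
}

#' Dice and Jaccard overlap
#'
#' Volume-overlap agreement between two binary masks:
#' `dice = 2|A n B| / (|A| + |B|)` and `jacc = |A n B| / |A u B|`.
#' When both masks are empty there is nothing to disagree about and both
#' scores are defined as 1.
#'
#' @param a,b [segmentation_mask()] objects or logical/0-1 arrays of equal
#'   shape.
#' @param label Label compared when masks are given (default 1, thrombus).
#' @return List with `dice` and `jacc`.
#' @export
dice_jaccard <- function(a, b, label = 1L) {
  A <- as_binary_volume(a, label)
  B <- as_binary_volume(b, label)
  if (!identical(dim(A), dim(B))) stop("mask shapes differ", call. = FALSE)
  nA <- sum(A); nB <- sum(B); nAB <- sum(A & B)
  if (nA + nB == 0L) return(list(dice = 1, jacc = 1))
  list(dice = 2 * nAB / (nA + nB), jacc = nAB / (nA + nB - nAB))
}

boundary_mm <- function(m2d, cal) {
  px <- contour_pixels(m2d)
  cbind(px[, 1L] * cal$pixel_spacing_row, px[, 2L] * cal$pixel_spacing_col)
}

#' Boundary distances: HD95 and average surface distance
#'
#' Distances between the boundary-pixel sets of two masks, in mm with
#' anisotropic spacing honored. Per frame, directed point-to-set distances
#' are computed in both directions and pooled (over frames too, for 3D
#' masks); `hd95` is the 95th percentile of the symmetric pool (linear
#' interpolation convention) and `asd` its mean. Frames empty in both masks
#' are skipped; a frame empty in exactly one mask makes the comparison
#' undefined and returns `NA` with a warning.
#'
#' @param a,b Masks as in [dice_jaccard()].
#' @param cal A [calibration()]; defaults to the calibration carried by `a`.
#' @param label Label compared when masks are given.
#' @return List with `hd95_mm`, `asd_mm`, and `n_pooled` distances.
#' @export
surface_distances <- function(a, b, cal = NULL, label = 1L) {
  if (is.null(cal) && inherits(a, "segmentation_mask")) cal <- a$calibration
  stopifnot(inherits(cal, "calibration"))
  A <- as_binary_volume(a, label)
  B <- as_binary_volume(b, label)
  if (!identical(dim(A), dim(B))) stop("mask shapes differ", call. = FALSE)
  pool <- numeric(0)
  for (t in seq_len(dim(A)[3L])) {
    mA <- A[, , t]; mB <- B[, , t]
    eA <- !any(mA); eB <- !any(mB)
    if (eA && eB) next
    if (eA || eB) {
      warning("frame ", t, " segmented in only one mask; surface distances undefined",
              call. = FALSE)
      return(list(hd95_mm = NA_real_, asd_mm = NA_real_, n_pooled = 0L))
    }
    sA <- boundary_mm(mA, cal)
    sB <- boundary_mm(mB, cal)
    pool <- c(pool, min_set_distances(sA, sB), min_set_distances(sB, sA))
  }
  if (length(pool) == 0L) {
    return(list(hd95_mm = 0, asd_mm = 0, n_pooled = 0L))
  }
  list(hd95_mm = unname(stats::quantile(pool, 0.95, type = 7)),
       asd_mm = mean(pool), n_pooled = length(pool))
}

#' Inter-/intrarater reliability report
#'
#' Pairwise agreement between two raters' masks of the same retrieval:
#' pooled Dice, Jaccard, HD95 and average surface distance, plus the
#' per-frame Dice/Jaccard table. The dice-jaccard identity
#' `dice = 2 jacc / (1 + jacc)` holds for every comparison.
#'
#' @param a,b [segmentation_mask()] objects of equal shape.
#' @param label Compared label (default 1, thrombus).
#' @return Object of class `"reliability_report"`.
#' @export
reliability_report <- function(a, b, label = 1L) {
  stopifnot(inherits(a, "segmentation_mask"), inherits(b, "segmentation_mask"))
  dj <- dice_jaccard(a, b, label)
  sd_ <- surface_distances(a, b, label = label)
  TT <- dim(a$voxels)[3L]
  per <- do.call(rbind, lapply(seq_len(TT), function(t) {
    x <- dice_jaccard(a$voxels[, , t] == label, b$voxels[, , t] == label)
    data.frame(t = t, dice = x$dice, jacc = x$jacc)
  }))
  structure(list(dice = dj$dice, jacc = dj$jacc,
                 hd95_mm = sd_$hd95_mm, asd_mm = sd_$asd_mm,
                 per_frame = per),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("reliability_report: DICE %.3f, JACC %.3f, HD95 %.3g mm, ASD %.3g mm\n",
              x$dice, x$jacc, x$hd95_mm, x$asd_mm))
  invisible(x)
}
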