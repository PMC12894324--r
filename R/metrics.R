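label_pixels <- function(mask, t, label = 1L) {
  which(mask$voxels[, , t] == label, arr.ind = TRUE)
}

# 4-neighbor boundary of a binary matrix: set pixels with at least one
# non-set 4-neighbor (frame edges count as outside).
contour_pixels <- function(mask2d) {
  d <- dim(mask2d)
  inner <- matrix(TRUE, d[1L], d[2L])
  pad <- function(dr, dc) {
    sh <- matrix(FALSE, d[1L], d[2L])
    r_src <- max(1L, 1L - dr):min(d[1L], d[1L] - dr)
    c_src <- max(1L, 1L - dc):min(d[2L], d[2L] - dc)
    sh[r_src + dr, c_src + dc] <- mask2d[r_src, c_src]
    sh
  }
  interior <- mask2d & pad(1L, 0L) & pad(-1L, 0L) & pad(0L, 1L) & pad(0L, -1L)
  which(mask2d & !interior, arr.ind = TRUE)
}

#' Per-frame thrombus geometry
#'
#' Derived shape record of the label-1 (thrombus) mask on one frame: pixel
#' count, length and width in mm (row/column extents times spacing), distal
#' and proximal tip Y-positions (extreme rows, distal = maximal row),
#' 4-neighbor contour pixels, geometric center of gravity (GCOG) and
#' physical area. An empty frame yields a record with `p = 0` and `NA`
#' geometry.
#'
#' @param mask A [segmentation_mask()].
#' @param t Frame index.
#' @return A list of class `"frame_geometry"`.
#' @export
frame_geometry <- function(mask, t) {
  stopifnot(inherits(mask, "segmentation_mask"))
  d <- dim(mask$voxels)
  if (t < 1L || t > d[3L]) stop("frame index out of range", call. = FALSE)
  cal <- mask$calibration
  px <- label_pixels(mask, t)
  p <- nrow(px)
  if (p == 0L) {
    g <- list(t = t, p = 0L, empty = TRUE, length_mm = NA_real_,
              width_mm = NA_real_, distal_tip_y_mm = NA_real_,
              proximal_tip_y_mm = NA_real_, contour = px,
              gcog = c(NA_real_, NA_real_), area_mm2 = 0)
    return(structure(g, class = "frame_geometry"))
  }
  rr <- range(px[, 1L])
  cc <- range(px[, 2L])
  m2d <- mask$voxels[, , t] == 1L
  structure(list(
    t = t, p = p, empty = FALSE,
    length_mm = (rr[2L] - rr[1L] + 1L) * cal$pixel_spacing_row,
    width_mm = (cc[2L] - cc[1L] + 1L) * cal$pixel_spacing_col,
    distal_tip_y_mm = rr[2L] * cal$pixel_spacing_row,
    proximal_tip_y_mm = rr[1L] * cal$pixel_spacing_row,
    contour = contour_pixels(m2d),
    gcog = c(mean(px[, 1L]), mean(px[, 2L])),
    area_mm2 = p * voxel_area_mm2(cal)
  ), class = "frame_geometry")
}

#' @rdname frame_geometry
#' @return `geometry_series()` returns the list of per-frame records for all
#'   frames; `geometry_table()` flattens it to a data frame (one row per
#'   frame, without the contour sets).
#' @export
geometry_series <- function(mask) {
  lapply(seq_len(dim(mask$voxels)[3L]), function(t) frame_geometry(mask, t))
}

#' @rdname frame_geometry
#' @param geoms A list of `frame_geometry` records.
#' @export
geometry_table <- function(geoms) {
  data.frame(
    t = vapply(geoms, `[[`, integer(1), "t"),
    p = vapply(geoms, `[[`, integer(1), "p"),
    length_mm = vapply(geoms, `[[`, numeric(1), "length_mm"),
    width_mm = vapply(geoms, `[[`, numeric(1), "width_mm"),
    distal_tip_y_mm = vapply(geoms, `[[`, numeric(1), "distal_tip_y_mm"),
    proximal_tip_y_mm = vapply(geoms, `[[`, numeric(1), "proximal_tip_y_mm"),
    gcog_row = vapply(geoms, function(g) g$gcog[1L], numeric(1)),
    gcog_col = vapply(geoms, function(g) g$gcog[2L], numeric(1)),
    area_mm2 = vapply(geoms, `[[`, numeric(1), "area_mm2")
  )
}

#' Thrombus deformation index D
#'
#' Mean relative absolute change of the thrombus pixel count over the
#' retrieval: `D = (1/N) * sum_{i=1..N} |p_i - p_0| / p_0`, with `p_0` the
#' count at the first frame and N the number of subsequent frames.
#' D is dimensionless; reported values are upscaled by 10^3 to make the
#' typical range readable. With `reference = "previous"` each frame is
#' instead compared with its predecessor (frame-to-frame variant).
#'
#' @param p Integer vector of per-frame thrombus pixel counts, first frame
#'   first.
#' @param reference `"first"` (the defining formula) or `"previous"`.
#' @return List with `D` (dimensionless) and `D_report` (`D * 1e3`).
#' @export
deformation <- function(p, reference = c("first", "previous")) {
  reference <- match.arg(reference)
  p <- as.numeric(p)
  if (length(p) < 2L) stop("need at least two frames", call. = FALSE)
  if (p[1L] <= 0) stop("initial pixel count p_0 must be positive", call. = FALSE)
  ref <- if (reference == "first") p[1L] else p[-length(p)]
  D <- mean(abs(p[-1L] - ref) / p[1L])
  list(D = D, D_report = D * 1e3)
}

#' Contour change CC
#'
#' For each frame transition t -> t+1, the mean over the contour pixels
#' `C_t` of the minimum Euclidean pixel distance to the next frame's
#' outline `O_{t+1}`; CC is the mean of these transition values. CC is
#' dimensionless (pixel units) and zero exactly when successive contours
#' coincide. Transitions whose next-frame outline is empty are skipped
#' (and counted in `n_skipped`); if every transition is empty an error is
#' raised.
#'
#' @param contours List of `n x 2` pixel-coordinate matrices, one per frame
#'   (the contour sets `C_t`).
#' @param outlines Optional list of outline sets `O_t`; defaults to
#'   `contours` (the two terms are used interchangeably).
#' @return List with `CC`, `per_transition` values and `n_skipped`.
#' @export
contour_change <- function(contours, outlines = contours) {
  if (length(contours) < 2L || length(outlines) != length(contours)) {
    stop("need matching contour/outline lists covering >= 2 frames",
         call. = FALSE)
  }
  TT <- length(contours)
  vals <- rep(NA_real_, TT - 1L)
  for (t in seq_len(TT - 1L)) {
    C_t <- contours[[t]]
    O_next <- outlines[[t + 1L]]
    if (is.null(C_t) || is.null(O_next) || nrow(C_t) == 0L || nrow(O_next) == 0L) next
    vals[t] <- mean(min_set_distances(C_t, O_next))
  }
  skipped <- sum(is.na(vals))
  if (skipped == TT - 1L) {
    stop("no transition has both a contour and a next-frame outline",
         call. = FALSE)
  }
  list(CC = mean(vals, na.rm = TRUE), per_transition = vals,
       n_skipped = skipped)
}

# For each point of `a` (n x 2), min Euclidean distance to the set `b`.
min_set_distances <- function(a, b) {
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  sqrt(apply(d2, 1L, min))
}

MIGRATION_BREAKS <- c(0, 1, 2.5, 4, Inf)
MIGRATION_LEVELS <- c("minimal", "moderate", "marked", "extensive")

#' Distal thrombus migration
#'
#' Peak displacement of the distal thrombus tip in the distal direction
#' relative to the first frame (proximal motion floors at 0 mm), classified
#' into the fixed half-open categories: minimal (< 1 mm), moderate (>= 1 to
#' < 2.5 mm), marked (>= 2.5 to < 4 mm) and extensive (>= 4 mm).
#'
#' @param geoms A list of [frame_geometry()] records (or a
#'   [segmentation_mask()], from which they are derived).
#' @return List with `migration_mm` and `category`.
#' @export
migration <- function(geoms) {
  if (inherits(geoms, "segmentation_mask")) geoms <- geometry_series(geoms)
  if (length(geoms) == 0L) stop("empty geometry series", call. = FALSE)
  tips <- vapply(geoms, `[[`, numeric(1), "distal_tip_y_mm")
  if (is.na(tips[1L])) {
    stop("thrombus absent at the first frame", call. = FALSE)
  }
  disp <- max(0, max(tips - tips[1L], na.rm = TRUE))
  list(migration_mm = disp, category = migration_category(disp))
}

#' @rdname migration
#' @param migration_mm Peak distal displacement in mm.
#' @export
migration_category <- function(migration_mm) {
  if (any(migration_mm < 0)) stop("migration must be >= 0 mm", call. = FALSE)
  as.character(cut(migration_mm, MIGRATION_BREAKS, MIGRATION_LEVELS,
                   right = FALSE))
}

#' Stent grip on the thrombus
#'
#' Mean per-frame change of the distance between the stent-tip Y-position
#' and the distal thrombus tip, in mm per slice. Positive values mean the
#' gap grows (the clot slips); near zero means the device carries the clot.
#'
#' @param geoms List of [frame_geometry()] records.
#' @param stent_tip_y_mm Numeric vector of per-frame stent-tip Y-positions
#'   (mm), same length as `geoms`.
#' @return Signed mean gap change in mm per slice.
#' @export
grip <- function(geoms, stent_tip_y_mm) {
  if (length(geoms) != length(stent_tip_y_mm)) {
    stop("geometry and stent-tip series differ in length", call. = FALSE)
  }
  if (length(geoms) < 2L) stop("need at least two frames", call. = FALSE)
  thr_tip <- vapply(geoms, `[[`, numeric(1), "distal_tip_y_mm")
  gap <- abs(stent_tip_y_mm - thr_tip)
  mean(diff(gap), na.rm = TRUE)
}

#' Retrieval kinematics from the GCOG track
#'
#' Physical motion quantities of the thrombus center of gravity: per-frame
#' speed (GCOG displacement in mm times frame rate), acceleration (speed
#' change times frame rate), lateral shift from the vessel middle axis
#' (`(gcog_col - axis_col) * col spacing`), and the mean speed over frames
#' with defined motion.
#'
#' @param geoms List of [frame_geometry()] records.
#' @param cal A [calibration()].
#' @param axis_col Column index of the operator-picked vessel middle axis
#'   (`NA` to skip the lateral-shift column).
#' @return Data frame with per-frame `speed_mm_s`, `accel_mm_s2`,
#'   `shift_mm`, plus attribute `mean_speed_mm_s`.
#' @export
kinematics <- function(geoms, cal, axis_col = NA) {
  stopifnot(inherits(cal, "calibration"))
  ok <- !vapply(geoms, `[[`, logical(1), "empty")
  if (sum(ok) < 2L) stop("need at least two frames with thrombus", call. = FALSE)
  g_row <- vapply(geoms, function(g) g$gcog[1L], numeric(1))
  g_col <- vapply(geoms, function(g) g$gcog[2L], numeric(1))
  TT <- length(geoms)
  speed <- rep(NA_real_, TT)
  step_mm <- sqrt((diff(g_row) * cal$pixel_spacing_row)^2 +
                  (diff(g_col) * cal$pixel_spacing_col)^2)
  speed[-1L] <- step_mm * cal$frame_rate
  accel <- rep(NA_real_, TT)
  accel[-(1:2)] <- diff(speed[-1L]) * cal$frame_rate
  shift <- (g_col - axis_col) * cal$pixel_spacing_col
  out <- data.frame(t = seq_len(TT), speed_mm_s = speed, accel_mm_s2 = accel,
                    shift_mm = shift)
  attr(out, "mean_speed_mm_s") <- mean(speed, na.rm = TRUE)
  out
}

#' Maximal shortening and elongation
#'
#' Per-frame positive parts of `L_0 - L_t` (shortening) and `L_t - L_0`
#' (elongation), maximized over the retrieval, in mm and as a percentage of
#' the initial length `L_0`.
#'
#' @param geoms List of [frame_geometry()] records.
#' @return List with `max_shortening_mm`, `max_shortening_pct`,
#'   `max_elongation_mm`, `max_elongation_pct`.
#' @export
shortening_elongation <- function(geoms) {
  L <- vapply(geoms, `[[`, numeric(1), "length_mm")
  if (is.na(L[1L]) || L[1L] <= 0) stop("initial length must be positive",
                                       call. = FALSE)
  sh <- pmax(L[1L] - L, 0)
  el <- pmax(L - L[1L], 0)
  list(max_shortening_mm = max(sh, na.rm = TRUE),
       max_shortening_pct = 100 * max(sh, na.rm = TRUE) / L[1L],
       max_elongation_mm = max(el, na.rm = TRUE),
       max_elongation_pct = 100 * max(el, na.rm = TRUE) / L[1L])
}

stent_tip_track <- function(mask) {
  cal <- mask$calibration
  vapply(seq_len(dim(mask$voxels)[3L]), function(t) {
    px <- label_pixels(mask, t, 2L)
    if (nrow(px) == 0L) return(NA_real_)
    max(px[, 1L]) * cal$pixel_spacing_row
  }, numeric(1))
}

#' Per-retrieval summary metrics
#'
#' Runs the full geometric analysis of a labeled retrieval mask: the
#' deformation index D (and its x10^3 report scale), the mean contour
#' change CC, peak distal migration with its category, maximal shortening
#' and elongation, stent grip (when label-2 voxels are present) and mean
#' GCOG speed. Frames with an empty thrombus mask are excluded from the
#' pixel-count and length series (propagation stops leave trailing empty
#' frames).
#'
#' @param mask A [segmentation_mask()].
#' @param axis_col Vessel middle-axis column for the lateral-shift track.
#' @param deformation_reference `"first"` or `"previous"`, see
#'   [deformation()].
#' @return An object of class `"retrieval_metrics"`.
#' @export
retrieval_metrics <- function(mask, axis_col = NA,
                              deformation_reference = "first") {
  stopifnot(inherits(mask, "segmentation_mask"))
  geoms <- geometry_series(mask)
  nonempty <- !vapply(geoms, `[[`, logical(1), "empty")
  if (!nonempty[1L]) stop("thrombus absent at the first frame", call. = FALSE)
  used <- geoms[nonempty]
  if (length(used) < 2L) stop("need thrombus on at least two frames", call. = FALSE)
  p <- vapply(used, `[[`, integer(1), "p")
  def <- deformation(p, deformation_reference)
  cc <- contour_change(lapply(used, `[[`, "contour"))
  mig <- migration(used)
  se <- shortening_elongation(used)
  kin <- kinematics(used, mask$calibration, axis_col)
  stent <- stent_tip_track(mask)
  grip_val <- if (all(is.na(stent))) NA_real_ else {
    keep <- nonempty & !is.na(stent)
    if (sum(keep) >= 2L) grip(geoms[keep], stent[keep]) else NA_real_
  }
  structure(list(
    D = def$D, D_report = def$D_report, CC = cc$CC,
    migration_mm = mig$migration_mm, migration_category = mig$category,
    max_shortening_mm = se$max_shortening_mm,
    max_shortening_pct = se$max_shortening_pct,
    max_elongation_mm = se$max_elongation_mm,
    max_elongation_pct = se$max_elongation_pct,
    grip_mm_per_slice = grip_val,
    mean_speed_mm_s = attr(kin, "mean_speed_mm_s"),
    n_frames_used = length(used),
    per_frame = {
      tab <- geometry_table(geoms)
      tab$speed_mm_s <- tab$accel_mm_s2 <- tab$shift_mm <- NA_real_
      tab[nonempty, c("speed_mm_s", "accel_mm_s2", "shift_mm")] <-
        kin[, c("speed_mm_s", "accel_mm_s2", "shift_mm")]
      tab
    }
  ), class = "retrieval_metrics")
}

#' @export
print.retrieval_metrics <- function(x, ...) {
  cat("retrieval_metrics\n")
  cat(sprintf("  deformation D: %.4g (x10^3: %.3g)\n", x$D, x$D_report))
  cat(sprintf("  contour change CC: %.3g px\n", x$CC))
  cat(sprintf("  distal migration: %.3g mm (%s)\n",
              x$migration_mm, x$migration_category))
  cat(sprintf("  max shortening: %.3g mm (%.1f%%), max elongation: %.3g mm (%.1f%%)\n",
              x$max_shortening_mm, x$max_shortening_pct,
              x$max_elongation_mm, x$max_elongation_pct))
  if (!is.na(x$grip_mm_per_slice)) {
    cat(sprintf("  stent grip: %.3g mm/slice\n", x$grip_mm_per_slice))
  }
  cat(sprintf("  mean GCOG speed: %.3g mm/s over %d frames\n",
              x$mean_speed_mm_s, x$n_frames_used))
  invisible(x)
}
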