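#' Phantom configuration
#'
#' Study-scale description of a synthetic retrieval scene: a static
#' contrast-filled vessel band, a radiolucent thrombus rendered as a
#' capsule (rounded rectangle) following per-frame motion, migration and
#' area-deformation schedules, and a radiopaque stent-tip marker proximal
#' to the clot. Defaults emulate the bench acquisition (6 frames/s,
#' 0.154-mm detector binned 2x to 0.308 mm/px on a 256 x 256 grid, 5-mm
#' lumen, retrieval speed about 5.5 mm/s) at desk scale: a 12-mm clot, a
#' short engagement phase with no drag followed by steady proximal
#' retraction at 0.924 mm/frame. Schedules are quantized to whole pixels
#' so that a rigid frame-to-frame translation is rendered exactly.
#'
#' @param height,width Frame size in pixels.
#' @param pixel_spacing_mm In-plane spacing, mm per pixel (isotropic).
#' @param frame_rate Frames per second.
#' @param n_frames Number of frames T.
#' @param axis_col Vessel middle-axis column.
#' @param lumen_width_mm Width of the contrast-filled band.
#' @param thrombus_length_mm,thrombus_width_mm Initial clot dimensions.
#' @param initial_distal_tip_mm Y-position of the distal clot tip at t = 1.
#' @param motion_mm Per-frame proximal displacement schedule (length T;
#'   entry t is the drag applied between frames t-1 and t, first entry 0).
#' @param migration_mm Per-frame distal tip offset schedule (length T).
#' @param area_schedule Per-frame area scale factors (length T, first 1);
#'   applied to the clot length.
#' @param jitter_amp_px,jitter_period_px Sinusoidal contour-jitter
#'   amplitude and period (0 = smooth capsule).
#' @param stent_offset_mm Gap between the marker and the proximal clot tip.
#' @param marker_size_mm Side of the square radiopaque marker.
#' @param noise_sd Additive Gaussian noise sd, in intensity units (the
#'   thrombus-over-lumen contrast is `intensities["thrombus"] -
#'   intensities["lumen"]` = 30 by default).
#' @param intensities Named vector: `background`, `lumen`, `thrombus`,
#'   `marker` grey levels.
#' @param allow_exit Permit the clot to cross the image border (clipped
#'   rendering) instead of failing validation.
#' @param split_frame,split_fragment_mm,split_gap_mm From `split_frame`
#'   onward the distal `split_fragment_mm` of the clot detaches, leaving a
#'   `split_gap_mm` gap (NULL = no fragmentation).
#' @param seed RNG seed for the noise.
#' @return Object of class `"phantom_config"`.
#' @export
phantom_config <- function(height = 256L, width = 256L,
                           pixel_spacing_mm = 0.308, frame_rate = 6,
                           n_frames = 40L, axis_col = 128L,
                           lumen_width_mm = 5,
                           thrombus_length_mm = 12, thrombus_width_mm = 3,
                           initial_distal_tip_mm = 61.6,
                           motion_mm = default_motion_schedule(n_frames,
                                                               pixel_spacing_mm),
                           migration_mm = rep(0, n_frames),
                           area_schedule = rep(1, n_frames),
                           jitter_amp_px = 0, jitter_period_px = 12,
                           stent_offset_mm = 2, marker_size_mm = 1.5,
                           noise_sd = 0,
                           intensities = c(background = 100, lumen = 60,
                                           thrombus = 90, marker = 30),
                           allow_exit = FALSE,
                           split_frame = NULL, split_fragment_mm = 4,
                           split_gap_mm = 1,
                           seed = 1L) {
  cfg <- structure(as.list(environment()), class = "phantom_config")
  stopifnot(length(cfg$motion_mm) == n_frames,
            length(cfg$migration_mm) == n_frames,
            length(cfg$area_schedule) == n_frames,
            all(cfg$area_schedule > 0), noise_sd >= 0,
            all(c("background", "lumen", "thrombus", "marker") %in%
                  names(intensities)))
  geo <- phantom_geometry(cfg)
  if (!allow_exit) {
    rows <- unlist(lapply(geo, function(g) c(g$prox_px, g$distal_px,
                                             g$marker_rows)))
    if (any(rows < 1L) || any(rows > height)) {
      stop("phantom geometry escapes the frame; enlarge the frame or set allow_exit",
           call. = FALSE)
    }
  }
  cfg
}

#' @rdname phantom_config
#' @details `default_motion_schedule()` is a 4-frame engagement pause
#'   followed by steady proximal drag of three pixels per frame
#'   (0.924 mm/frame at the default spacing, i.e. about 5.5 mm/s at
#'   6 frames/s).
#' @export
default_motion_schedule <- function(n_frames, pixel_spacing_mm = 0.308) {
  step <- 3 * pixel_spacing_mm
  c(rep(0, min(4L, n_frames)), rep(step, max(0L, n_frames - 4L)))
}

#' @rdname phantom_config
#' @param peak_mm Peak distal offset of the migration episode.
#' @param ramp_frames Frames over which the offset ramps up to the peak
#'   (it then persists: initial migration followed by stabilization).
#'   The default completes inside the engagement pause of
#'   [default_motion_schedule()], so the peak is realized before proximal
#'   drag begins.
#' @export
migration_episode <- function(n_frames, peak_mm, ramp_frames = 3L,
                              pixel_spacing_mm = 0.308) {
  ramp <- seq(0, peak_mm, length.out = ramp_frames + 1L)[-1L]
  out <- c(0, ramp, rep(peak_mm, max(0L, n_frames - ramp_frames - 1L)))
  # quantize to whole pixels so translations stay rigid
  round(out[seq_len(n_frames)] / pixel_spacing_mm) * pixel_spacing_mm
}

# Per-frame integer-pixel geometry derived from the schedules.
phantom_geometry <- function(cfg) {
  sp <- cfg$pixel_spacing_mm
  tip_mm <- cfg$initial_distal_tip_mm - cumsum(cfg$motion_mm) + cfg$migration_mm
  len_px0 <- round(cfg$thrombus_length_mm / sp)
  marker_px <- max(1L, round(cfg$marker_size_mm / sp))
  gap_px <- round(cfg$stent_offset_mm / sp)
  lapply(seq_len(cfg$n_frames), function(t) {
    distal <- round(tip_mm[t] / sp)
    len <- max(1L, round(len_px0 * cfg$area_schedule[t]))
    prox <- distal - len + 1L
    split <- !is.null(cfg$split_frame) && t >= cfg$split_frame
    marker_top <- prox - gap_px - marker_px + 1L
    list(t = t, distal_px = distal, prox_px = prox, length_px = len,
         split = split,
         frag_px = if (split) max(1L, round(cfg$split_fragment_mm / sp)) else 0L,
         gap_px_split = if (split) max(1L, round(cfg$split_gap_mm / sp)) else 0L,
         marker_rows = marker_top:(marker_top + marker_px - 1L),
         marker_px = marker_px)
  })
}

# Rasterize one capsule spanning rows [prox, distal] with half-width
# profile: full radius in the body, circular caps at both ends, plus
# optional sinusoidal jitter. Returns a logical matrix.
rasterize_capsule <- function(height, width, prox, distal, axis_col,
                              radius_px, jitter_amp, jitter_period, phase) {
  m <- matrix(FALSE, height, width)
  rows <- prox:distal
  # overhang from integer row offsets only: keeps the rasterization exactly
  # translation invariant (no position-dependent float residue at the tips)
  overhang <- pmax(0, radius_px - (rows - prox), radius_px - (distal - rows))
  hw <- sqrt(pmax(0, radius_px^2 - overhang^2))
  if (jitter_amp > 0) {
    hw <- pmax(0.5, hw + jitter_amp * sin(2 * pi * (rows - distal) /
                                            jitter_period + phase))
  }
  keep <- rows >= 1L & rows <= height & hw > 0
  for (i in which(keep)) {
    c0 <- max(1L, axis_col - floor(hw[i]))
    c1 <- min(width, axis_col + floor(hw[i]))
    if (c0 <= c1) m[rows[i], c0:c1] <- TRUE
  }
  m
}

thrombus_mask_at <- function(cfg, g) {
  radius <- (cfg$thrombus_width_mm / cfg$pixel_spacing_mm) / 2
  phase <- if (cfg$jitter_amp_px > 0) 2 * pi * g$t / cfg$n_frames else 0
  if (!g$split) {
    return(rasterize_capsule(cfg$height, cfg$width, g$prox_px, g$distal_px,
                             cfg$axis_col, radius, cfg$jitter_amp_px,
                             cfg$jitter_period_px, phase))
  }
  # detached distal fragment + shortened main body
  frag_top <- g$distal_px - g$frag_px + 1L
  main_distal <- frag_top - g$gap_px_split - 1L
  main <- rasterize_capsule(cfg$height, cfg$width, g$prox_px, main_distal,
                            cfg$axis_col, radius, cfg$jitter_amp_px,
                            cfg$jitter_period_px, phase)
  frag <- rasterize_capsule(cfg$height, cfg$width, frag_top, g$distal_px,
                            cfg$axis_col, radius, 0, cfg$jitter_period_px, 0)
  main | frag
}

#' Generate a synthetic retrieval phantom
#'
#' Renders the calibrated frame series, the ground-truth label mask
#' (1 thrombus, 2 stent-tip marker) and a truth record computed from the
#' scene geometry without any segmentation: per-frame pixel counts and tip
#' positions, the deformation index of the rendered counts (`d`,
#' `d_report`) next to the analytic schedule value (`d_schedule`, the mean
#' relative area-factor change), peak distal migration and its category,
#' the scheduled mean GCOG speed, the marker track, and an `in_frame` flag
#' marking frames where the clot lies fully inside the field of view.
#'
#' @param cfg A [phantom_config()].
#' @return List with elements `series` ([frame_series()]), `truth_mask`
#'   ([segmentation_mask()]) and `truth` (list).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  cal <- calibration(cfg$pixel_spacing_mm, cfg$pixel_spacing_mm,
                     cfg$frame_rate)
  geo <- phantom_geometry(cfg)
  H <- cfg$height; W <- cfg$width; TT <- cfg$n_frames
  ints <- cfg$intensities
  band_cols <- band_columns(cfg)
  base_frame <- matrix(ints[["background"]], H, W)
  base_frame[, band_cols] <- ints[["lumen"]]
  frames <- array(0, dim = c(H, W, TT))
  vox <- array(0L, dim = c(H, W, TT))
  set.seed(cfg$seed)
  for (t in seq_len(TT)) {
    g <- geo[[t]]
    thr <- thrombus_mask_at(cfg, g)
    f <- base_frame
    f[thr] <- ints[["thrombus"]]
    mk_rows <- g$marker_rows[g$marker_rows >= 1L & g$marker_rows <= H]
    half <- floor(g$marker_px / 2)
    mk_cols <- max(1L, cfg$axis_col - half):min(W, cfg$axis_col + half)
    mk <- matrix(FALSE, H, W)
    if (length(mk_rows)) mk[mk_rows, mk_cols] <- TRUE
    f[mk] <- ints[["marker"]]
    if (cfg$noise_sd > 0) f <- f + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W)
    frames[, , t] <- f
    v <- matrix(0L, H, W)
    v[thr] <- 1L
    v[mk] <- 2L
    vox[, , t] <- v
  }
  series <- frame_series(frames, cal)
  truth_mask <- segmentation_mask(vox, cal)
  truth <- phantom_truth(cfg, geo, truth_mask)
  list(series = series, truth_mask = truth_mask, truth = truth, config = cfg)
}

band_columns <- function(cfg) {
  half <- floor((cfg$lumen_width_mm / cfg$pixel_spacing_mm) / 2)
  max(1L, cfg$axis_col - half):min(cfg$width, cfg$axis_col + half)
}

phantom_truth <- function(cfg, geo, truth_mask) {
  sp <- cfg$pixel_spacing_mm
  p <- vapply(seq_len(cfg$n_frames),
              function(t) sum(truth_mask$voxels[, , t] == 1L), integer(1))
  tip_mm <- vapply(geo, `[[`, numeric(1), "distal_px") * sp
  in_frame <- vapply(geo, function(g) {
    g$prox_px >= 1L && g$distal_px <= cfg$height
  }, logical(1))
  def <- deformation(p)
  a <- cfg$area_schedule
  center_px <- vapply(geo, function(g) (g$prox_px + g$distal_px) / 2, numeric(1))
  speed <- abs(diff(center_px)) * sp * cfg$frame_rate
  disp <- max(0, max(tip_mm - tip_mm[1L]))
  list(p_counts = p, d = def$D, d_report = def$D_report,
       d_schedule = mean(abs(a[-1L] - a[1L]) / a[1L]),
       distal_tip_y_mm = tip_mm,
       migration_mm = disp, migration_category = migration_category(disp),
       mean_speed_mm_s = mean(speed),
       stent_tip_y_mm = vapply(geo, function(g) max(g$marker_rows), numeric(1)) * sp,
       in_frame = in_frame)
}

#' Deterministic fixture catalogue
#'
#' Small set of phantom configurations exercising the behaviors the
#' pipeline must reproduce: one phantom per migration category (minimal,
#' moderate, marked, extensive), a fragmentation-like split, and a
#' failure mode where the clot leaves the field of view before the series
#' ends. Each entry carries its configuration and the expected qualitative
#' outcome.
#'
#' @param n_frames,noise_sd Passed through to every configuration.
#' @return Named list of `list(cfg, expect)` entries.
#' @export
default_fixture_suite <- function(n_frames = 40L, noise_sd = 0) {
  mk <- function(..., expect) {
    list(cfg = phantom_config(n_frames = n_frames, noise_sd = noise_sd, ...),
         expect = expect)
  }
  sp <- 0.308
  list(
    minimal = mk(expect = list(category = "minimal")),
    moderate = mk(migration_mm = migration_episode(n_frames, 5 * sp),
                  expect = list(category = "moderate")),
    marked = mk(migration_mm = migration_episode(n_frames, 9 * sp),
                expect = list(category = "marked")),
    extensive = mk(migration_mm = migration_episode(n_frames, 14 * sp),
                   expect = list(category = "extensive")),
    split = mk(split_frame = 20L, expect = list(count_drop_at = 20L)),
    exit = mk(initial_distal_tip_mm = 18,
              motion_mm = c(rep(0, 2L), rep(3 * sp, n_frames - 2L)),
              allow_exit = TRUE,
              expect = list(exits = TRUE))
  )
}
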