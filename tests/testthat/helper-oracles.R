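# Independent brute-force oracles. These deliberately use pixel-queue /
# double-loop algorithms, not the package's vectorized implementations.

neighbor_offsets <- function(connectivity) {
  four <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 4) four
  else rbind(four, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
}

# Seeded threshold flood fill by explicit depth-first pixel traversal.
bf_flood <- function(frame, seeds, lo, hi, connectivity) {
  d <- dim(frame)
  inset <- frame >= lo & frame <= hi
  visited <- matrix(FALSE, d[1], d[2])
  offs <- neighbor_offsets(connectivity)
  stack <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  while (length(stack)) {
    px <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- px[1]; c <- px[2]
    if (r < 1 || r > d[1] || c < 1 || c > d[2]) next
    if (!inset[r, c] || visited[r, c]) next
    visited[r, c] <- TRUE
    for (k in seq_len(nrow(offs))) {
      stack[[length(stack) + 1L]] <- c(r + offs[k, 1], c + offs[k, 2])
    }
  }
  visited
}

# Boundary pixels by explicit 4-neighbor inspection.
bf_boundary <- function(m) {
  d <- dim(m)
  out <- NULL
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (!m[r, c]) next
    nb <- c(
      if (r > 1) m[r - 1, c] else FALSE,
      if (r < d[1]) m[r + 1, c] else FALSE,
      if (c > 1) m[r, c - 1] else FALSE,
      if (c < d[2]) m[r, c + 1] else FALSE
    )
    if (any(!nb)) out <- rbind(out, c(r, c))
  }
  out
}

# Mean over points of a of the min distance to b, by double loop.
bf_mean_min_dist <- function(a, b) {
  total <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      dd <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (dd < best) best <- dd
    }
    total <- total + best
  }
  total / nrow(a)
}

bf_directed_dists <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2))
  }, numeric(1))
}

# U statistic by pairwise win + half-tie count.
bf_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Exact two-sided rank-sum p by enumeration of all group assignments of the
# pooled sample (permutation null).
enum_ranksum_p <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  picks <- utils::combn(length(pool), m)
  u_obs <- bf_U(x, y)
  center <- m * length(y) / 2
  stat <- abs(u_obs - center)
  us <- apply(picks, 2, function(idx) bf_U(pool[idx], pool[-idx]))
  mean(abs(us - center) >= stat - 1e-12)
}

# Two-sided 2x2 Fisher p by hypergeometric enumeration.
enum_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a_range, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_label_mask <- function(h, w, t, prob = 0.3) {
  array(sample(0:1, h * w * t, replace = TRUE, prob = c(1 - prob, prob)),
        dim = c(h, w, t))
}

# Normalized-series stand-in built directly from a frame array, for
# controlled segmentation scenarios.
fake_ns <- function(frames, cal = calibration(1, 1, 6)) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  structure(list(frames = frames, calibration = cal,
                 baseline = matrix(0, dim(frames)[1], dim(frames)[2]),
                 source_roi = NULL),
            class = "normalized_series")
}

# Small moving-blob normalized series: value `value` inside a square blob
# whose top-left corner follows `positions` (T x 2), zero elsewhere.
blob_series <- function(h, w, positions, side = 3L, value = 10) {
  TT <- nrow(positions)
  arr <- array(0, dim = c(h, w, TT))
  for (t in seq_len(TT)) {
    r0 <- positions[t, 1]; c0 <- positions[t, 2]
    rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
    rows <- rows[rows >= 1 & rows <= h]; cols <- cols[cols >= 1 & cols <= w]
    arr[rows, cols, t] <- value
  }
  fake_ns(arr)
}

# Default-phantom segmentation harness: crop to the vessel ROI, normalize,
# segment from centerline drag paths, and return everything needed for
# truth comparison.
segment_phantom <- function(ph, connectivity = 8L) {
  cfg <- ph$config
  half_roi <- 20L
  c0 <- cfg$axis_col - half_roi; c1 <- cfg$axis_col + half_roi
  roi <- roi_box(1L, cfg$height, c0, c1)
  ns <- normalize_series(crop_series(ph$series, roi))
  axis_roi <- cfg$axis_col - c0 + 1L
  geo1 <- thrombotrack:::phantom_geometry(cfg)[[1]]
  path_rows <- (geo1$prox_px + 3L):(geo1$distal_px - 3L)
  tp <- seed_path(1L, cbind(path_rows, axis_roi))
  mrows <- geo1$marker_rows
  sp <- seed_path(1L, cbind(mrows, axis_roi))
  mask <- segment_retrieval(ns, tp, sp, connectivity)
  truth <- segmentation_mask(ph$truth_mask$voxels[, c0:c1, , drop = FALSE],
                             ph$truth_mask$calibration)
  list(mask = mask, truth = truth, ns = ns, axis_col = axis_roi, roi = roi)
}

per_frame_dice <- function(mask, truth, frames = NULL, label = 1L) {
  TT <- dim(mask$voxels)[3]
  if (is.null(frames)) frames <- seq_len(TT)
  vapply(frames, function(t) {
    dice_jaccard(mask$voxels[, , t] == label,
                 truth$voxels[, , t] == label)$dice
  }, numeric(1))
}
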