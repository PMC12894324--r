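cal_half <- calibration(0.5, 0.5, 6)

solid_mask <- function(rows, cols, t_total = 1L, cal = cal_half, h = 20L, w = 20L) {
  vox <- array(0L, dim = c(h, w, t_total))
  for (t in seq_len(t_total)) vox[rows, cols, t] <- 1L
  segmentation_mask(vox, cal)
}

test_that("frame geometry counts pixels and converts extents to mm", {
  g <- frame_geometry(solid_mask(3:5, 2:5), 1)  # 3 x 4 rectangle, 0.5 mm px
  expect_equal(g$p, 12L)
  expect_equal(g$length_mm, 1.5)
  expect_equal(g$width_mm, 2.0)
  expect_equal(g$area_mm2, 12 * 0.25)
  expect_equal(g$distal_tip_y_mm, 5 * 0.5)
  expect_equal(g$proximal_tip_y_mm, 3 * 0.5)
  expect_equal(g$gcog, c(4, 3.5))
  # interior pixel count: 3x4 solid has 12 - 2 interior = 10 boundary px
  expect_equal(nrow(g$contour), 10)

  single <- frame_geometry(solid_mask(7, 7), 1)
  expect_equal(single$length_mm, 0.5)
  expect_equal(single$width_mm, 0.5)
  expect_equal(unname(single$gcog), c(7, 7))
  expect_equal(unname(single$contour), matrix(c(7L, 7L), 1))

  empty <- frame_geometry(segmentation_mask(array(0L, c(4, 4, 1)), cal_half), 1)
  expect_true(empty$empty)
  expect_equal(empty$p, 0L)
  expect_true(is.na(empty$length_mm))
})

test_that("contour pixels agree with the explicit-neighbor oracle", {
  set.seed(3)
  for (rep in 1:25) {
    m <- matrix(runif(64) < 0.4, 8, 8)
    got <- thrombotrack:::contour_pixels(m)
    want <- bf_boundary(m)
    if (is.null(want)) expect_equal(nrow(got), 0)
    else expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  }
})

test_that("deformation D follows the printed formula and its invariances", {
  expect_equal(deformation(c(100, 100, 100))$D, 0)

  d <- deformation(c(100, 110, 90, 100))
  expect_equal(d$D, (10 + 10 + 0) / (3 * 100))
  expect_equal(d$D_report, 1000 * 2 / 30)

  # scale invariance of the ratio
  expect_equal(deformation(2 * c(100, 110, 90, 100))$D, d$D)

  # D = 0 iff all counts equal the first
  expect_true(deformation(c(50, 50, 51))$D > 0)

  # frame-to-frame variant
  prev <- deformation(c(100, 110, 90, 100), reference = "previous")
  expect_equal(prev$D, (10 + 20 + 10) / (3 * 100))

  expect_error(deformation(c(0, 10)), "positive")
  expect_error(deformation(100), "two frames")
})

test_that("contour change matches hand values and the brute-force oracle", {
  sq <- function(dr = 0, dc = 0) {
    px <- expand.grid(r = 2:5, c = 2:5)
    px <- px[px$r %in% c(2, 5) | px$c %in% c(2, 5), ]
    cbind(px$r + dr, px$c + dc)
  }
  # identical contours: zero
  expect_equal(contour_change(list(sq(), sq(), sq()))$CC, 0)

  # 3-4-5 distance
  expect_equal(contour_change(list(cbind(1, 1), cbind(4, 5)))$CC, 5)

  # square outline shifted 1 px: compare with the double-loop oracle
  cc <- contour_change(list(sq(), sq(0, 1)))
  expect_equal(cc$CC, bf_mean_min_dist(sq(), sq(0, 1)))

  # directed asymmetry: t -> t+1 is not t+1 -> t in general
  a <- cbind(1:6, 1)
  b <- cbind(3, 1)
  expect_equal(contour_change(list(a, b))$CC, bf_mean_min_dist(a, b))
  expect_equal(contour_change(list(b, a))$CC, bf_mean_min_dist(b, a))
  expect_false(isTRUE(all.equal(bf_mean_min_dist(a, b), bf_mean_min_dist(b, a))))

  # random masks against the oracle
  set.seed(21)
  for (rep in 1:20) {
    c1 <- which(matrix(runif(49) < 0.3, 7, 7), arr.ind = TRUE)
    c2 <- which(matrix(runif(49) < 0.3, 7, 7), arr.ind = TRUE)
    if (nrow(c1) == 0 || nrow(c2) == 0) next
    expect_equal(contour_change(list(c1, c2))$CC, bf_mean_min_dist(c1, c2))
  }

  # transitions touching an empty frame are skipped, all-empty errors
  sk <- contour_change(list(sq(), NULL, sq(), sq()))
  expect_equal(sk$n_skipped, 2)
  expect_equal(sk$CC, 0)
  expect_error(contour_change(list(sq(), NULL)), "no transition")
})

test_that("migration uses the peak distal displacement with fixed categories", {
  expect_equal(migration_category(0.9), "minimal")
  expect_equal(migration_category(1.0), "moderate")
  expect_equal(migration_category(2.5), "marked")
  expect_equal(migration_category(4.0), "extensive")
  expect_equal(migration_category(4.2), "extensive")

  # categories partition [0, inf): every value gets exactly one category
  grid <- seq(0, 8, by = 0.01)
  cats <- migration_category(grid)
  expect_false(anyNA(cats))
  expect_equal(sort(unique(cats)),
               sort(c("minimal", "moderate", "marked", "extensive")))

  mk_geoms <- function(tips_mm) {
    lapply(tips_mm, function(y) {
      g <- frame_geometry(solid_mask(3:4, 3:4), 1)
      g$distal_tip_y_mm <- y
      g
    })
  }
  # peak, not final, displacement; proximal-only motion floors at zero
  m <- migration(mk_geoms(c(10, 11.8, 10.5)))
  expect_equal(m$migration_mm, 1.8)
  expect_equal(m$category, "moderate")
  m0 <- migration(mk_geoms(c(10, 9, 8)))
  expect_equal(m0$migration_mm, 0)
  expect_equal(m0$category, "minimal")
})

test_that("grip is the mean change of the tip-to-tip gap", {
  mk_geoms <- function(tips_mm) {
    lapply(tips_mm, function(y) {
      g <- frame_geometry(solid_mask(3:4, 3:4), 1)
      g$distal_tip_y_mm <- y
      g
    })
  }
  # both tips translate identically: zero
  g <- mk_geoms(c(10, 9, 8, 7))
  expect_equal(grip(g, c(12, 11, 10, 9)), 0)
  # gap grows 0.2 mm per frame
  g2 <- mk_geoms(rep(10, 5))
  expect_equal(grip(g2, 12 + 0.2 * (0:4)), 0.2)
  # signed: shrinking gap is negative
  expect_equal(grip(g2, 12 - 0.2 * (0:4)), -0.2)
  expect_error(grip(g2[1], 12), "two frames")
  expect_error(grip(g2, c(1, 2)), "length")
})

test_that("kinematics converts GCOG motion into speed and acceleration", {
  cal <- calibration(0.154, 0.154, 6)
  mk <- function(rows) lapply(rows, function(r) {
    g <- frame_geometry(solid_mask(3:4, 3:4, cal = cal), 1)
    g$gcog <- c(r, 10)
    g$empty <- FALSE
    g
  })
  # 6 px/frame at 0.154 mm and 6 fps -> 5.544 mm/s
  kin <- kinematics(mk(c(10, 16, 22)), cal)
  expect_equal(kin$speed_mm_s[-1], c(5.544, 5.544))
  expect_equal(attr(kin, "mean_speed_mm_s"), 5.544)
  expect_equal(kin$accel_mm_s2[3], 0)

  still <- kinematics(mk(c(10, 10, 10)), cal)
  expect_equal(attr(still, "mean_speed_mm_s"), 0)
  expect_equal(still$accel_mm_s2[3], 0)

  expect_error(kinematics(mk(10), cal), "two frames")

  # lateral shift from the configured vessel axis
  sh <- kinematics(mk(c(10, 16)), cal, axis_col = 8)
  expect_equal(sh$shift_mm, rep((10 - 8) * 0.154, 2))
})

test_that("speed integrates back to the GCOG path length", {
  set.seed(8)
  cal <- calibration(0.2, 0.3, 5)
  rows <- cumsum(c(10, rnorm(9)))
  cols <- cumsum(c(10, rnorm(9)))
  geoms <- Map(function(r, c) {
    g <- frame_geometry(solid_mask(3:4, 3:4, cal = cal), 1)
    g$gcog <- c(r, c); g$empty <- FALSE; g
  }, rows, cols)
  kin <- kinematics(geoms, cal)
  path_len <- sum(sqrt((diff(rows) * 0.2)^2 + (diff(cols) * 0.3)^2))
  expect_equal(sum(kin$speed_mm_s, na.rm = TRUE) / 5, path_len)
})

test_that("shortening/elongation are positive parts relative to L0", {
  mk <- function(lens) lapply(lens, function(L) {
    g <- frame_geometry(solid_mask(3:4, 3:4), 1)
    g$length_mm <- L
    g
  })
  se <- shortening_elongation(mk(c(40, 35, 38)))
  expect_equal(se$max_shortening_mm, 5)
  expect_equal(se$max_shortening_pct, 12.5)
  expect_equal(se$max_elongation_mm, 0)

  se2 <- shortening_elongation(mk(c(40, 42)))
  expect_equal(se2$max_elongation_mm, 2)
  expect_equal(se2$max_elongation_pct, 5)

  se3 <- shortening_elongation(mk(c(40, 40, 40)))
  expect_equal(se3$max_shortening_mm + se3$max_elongation_mm, 0)

  expect_error(shortening_elongation(mk(c(0, 1))), "positive")
})

test_that("retrieval_metrics assembles a consistent summary", {
  ph <- generate_phantom(phantom_config())
  seg <- segment_phantom(ph)
  m <- retrieval_metrics(seg$mask, axis_col = seg$axis_col)
  expect_s3_class(m, "retrieval_metrics")
  expect_equal(m$D, ph$truth$d)
  expect_equal(m$D_report, m$D * 1e3)
  expect_equal(m$migration_category, ph$truth$migration_category)
  expect_true(m$CC >= 0)
  expect_equal(nrow(m$per_frame), 40)
  expect_output(print(m), "deformation D")
})
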