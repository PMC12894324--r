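test_that("the threshold interval is the min/max under the drag path", {
  arr <- array(0, dim = c(4, 4, 2))
  arr[1, 1, 1] <- 3.0; arr[2, 1, 1] <- 5.5; arr[3, 1, 1] <- 4.0
  ns <- fake_ns(arr)
  iv <- interval_from_path(ns, seed_path(1, rbind(c(1, 1), c(2, 1), c(3, 1))))
  expect_equal(iv$lo, 3.0)
  expect_equal(iv$hi, 5.5)

  arr[2, 2, 2] <- 7
  iv1 <- interval_from_path(fake_ns(arr), seed_path(2, cbind(2, 2)))
  expect_equal(c(iv1$lo, iv1$hi), c(7, 7))

  expect_error(interval_from_path(ns, seed_path(1, cbind(9, 1))), "bounds")
  expect_error(interval_from_path(ns, seed_path(3, cbind(1, 1))), "bounds")
  expect_error(seed_path(1, matrix(numeric(0), ncol = 2)), "non-empty")
})

test_that("flood fill keeps exactly the seeded in-interval component", {
  f <- matrix(0, 5, 5)
  f[2:3, 2:3] <- 5      # seeded region
  f[5, 5] <- 5          # disjoint in-interval region
  iv <- threshold_interval(4, 6)
  m <- flood_fill_2d(f, cbind(2, 2), iv)
  expect_identical(m, f == 5 & row(f) < 5)
  expect_false(m[5, 5])

  # out-of-interval seed contributes nothing
  expect_false(any(flood_fill_2d(f, cbind(1, 1), iv)))

  # a mixed seed set: only in-interval seeds matter
  m2 <- flood_fill_2d(f, rbind(c(1, 1), c(5, 5)), iv)
  expect_true(m2[5, 5] && sum(m2) == 1)

  expect_error(flood_fill_2d(f, matrix(numeric(0), ncol = 2), iv), "non-empty")
  expect_error(flood_fill_2d(f, cbind(6, 1), iv), "bounds")
})

test_that("4- vs 8-connectivity differ exactly on diagonal touching", {
  f <- matrix(0, 3, 3)
  f[1, 1] <- f[2, 2] <- 1
  iv <- threshold_interval(1, 1)
  expect_equal(sum(flood_fill_2d(f, cbind(1, 1), iv, 4)), 1)
  expect_equal(sum(flood_fill_2d(f, cbind(1, 1), iv, 8)), 2)
})

test_that("flood fill equals the pixel-queue oracle on random grids", {
  set.seed(99)
  for (rep in 1:120) {
    f <- matrix(sample(0:1, 36, replace = TRUE), 6, 6)
    seed <- cbind(sample(6, 1), sample(6, 1))
    for (conn in c(4L, 8L)) {
      got <- flood_fill_2d(f, seed, threshold_interval(1, 1), conn)
      want <- bf_flood(f, seed, 1, 1, conn)
      expect_identical(got, want)
    }
  }
})

test_that("widening the interval never shrinks the mask", {
  set.seed(5)
  f <- matrix(runif(49, 0, 10), 7, 7)
  seed <- cbind(4, 4)
  prev <- NULL
  for (w in seq(0.5, 10, by = 0.5)) {
    m <- flood_fill_2d(f, seed, threshold_interval(f[4, 4] - w, f[4, 4] + w))
    if (!is.null(prev)) expect_true(all(m[prev]))
    prev <- m
  }
})

test_that("temporal propagation tracks an overlapping blob and stops on a jump", {
  # blob translating 1 px/frame with overlap: tracked in all frames
  pos <- cbind(2:6, 3)
  ns <- blob_series(12, 8, pos)
  iv <- threshold_interval(10, 10)
  m0 <- ns$frames[, , 1] == 10
  out <- propagate_temporal(ns, 1, m0, iv)
  for (t in 1:5) expect_equal(out[, , t], ns$frames[, , t] == 10)

  # zero-overlap jump: propagation stops at the jump
  pos2 <- rbind(c(2, 2), c(3, 2), c(9, 5), c(9, 5))
  ns2 <- blob_series(14, 8, pos2)
  out2 <- propagate_temporal(ns2, 1, ns2$frames[, , 1] == 10, iv)
  expect_true(any(out2[, , 2]))
  expect_false(any(out2[, , 3]))
  expect_false(any(out2[, , 4]))
})

test_that("propagation from the last frame runs backward only", {
  pos <- cbind(2:5, 2)
  ns <- blob_series(10, 7, pos)
  iv <- threshold_interval(10, 10)
  out <- propagate_temporal(ns, 4, ns$frames[, , 4] == 10, iv)
  for (t in 1:4) expect_equal(out[, , t], ns$frames[, , t] == 10)
})

test_that("propagation is deterministic and idempotent in its inputs", {
  pos <- cbind(c(2, 3, 4, 5, 6), 3)
  ns <- blob_series(12, 8, pos)
  iv <- threshold_interval(10, 10)
  m0 <- ns$frames[, , 3] == 10
  a <- propagate_temporal(ns, 3, m0, iv)
  b <- propagate_temporal(ns, 3, m0, iv)
  expect_identical(a, b)
  # re-seeding from its own frame-3 output changes nothing
  c_ <- propagate_temporal(ns, 3, a[, , 3], iv)
  expect_identical(a, c_)
})

test_that("propagation stops once the structure only touches the border", {
  # blob slides off the top edge
  pos <- cbind(c(4, 2, 1, 0, -2), 3)
  ns <- blob_series(10, 8, pos, side = 3)
  iv <- threshold_interval(10, 10)
  out <- propagate_temporal(ns, 1, ns$frames[, , 1] == 10, iv)
  expect_true(any(out[, , 2]))
  stopped <- which(vapply(1:5, function(t) !any(out[, , t]), logical(1)))
  expect_true(length(stopped) > 0)
  expect_true(all(stopped > 2))
})

test_that("segment_retrieval labels thrombus 1 and stent 2, stent wins overlap", {
  arr <- array(0, dim = c(10, 10, 3))
  arr[2:6, 2:4, ] <- 10    # thrombus intensity
  arr[5:7, 2:4, ] <- -8    # marker intensity, rows 5:6 carved out of thrombus
  arr[2:4, 2:4, ] <- 10
  ns <- fake_ns(arr)
  mask <- segment_retrieval(ns, seed_path(1, cbind(2:4, 3)),
                            seed_path(1, cbind(5:7, 3)))
  expect_equal(sort(unique(as.integer(mask$voxels))), c(0L, 1L, 2L))
  expect_true(all(mask$voxels[5:7, 2:4, ] == 2L))
  expect_true(all(mask$voxels[2:4, 2:4, ] == 1L))

  # a drag on uniform background floods the background component: the
  # interval always contains the path's own pixels, so the seed frame can
  # never come out empty (operator error is visible, not silently dropped)
  m2 <- segment_retrieval(ns, seed_path(1, cbind(2:4, 3)),
                          seed_path(1, cbind(9, 9)))
  expect_gt(sum(m2$voxels == 2L), 0)
  expect_true(all(which(m2$voxels[, , 1] == 2L, arr.ind = TRUE)[, 1] >= 1))
})

test_that("label-2 precedence assigns exactly the overlapping voxels", {
  # same intensity for both structures: both paths segment the same region
  arr <- array(0, dim = c(8, 8, 2))
  arr[2:5, 2:5, ] <- 7
  ns <- fake_ns(arr)
  mask <- segment_retrieval(ns, seed_path(1, cbind(2, 2)),
                            seed_path(1, cbind(3, 3)))
  expect_equal(sum(mask$voxels == 2L), 2 * 16)  # overlap fully relabeled
  expect_equal(sum(mask$voxels == 1L), 0)
})
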