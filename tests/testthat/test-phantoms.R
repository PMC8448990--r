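# Synthetic canal phantom generator.

test_that("centerline arc length matches the analytic circumference fraction", {
  spec <- smallPhantomSpec(seed = 3)
  pts <- canalCenterline(spec, 0L, seed = 11)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  # polyline length of a (2/3) arc of a 6.5 mm circle
  expect_equal(sum(seg), (2 / 3) * pi * 6.5, tolerance = 0.01)
  # dense sampling: point spacing at most half the tube radius
  expect_lte(max(seg), spec@tubeRadiusMm / 2 + 1e-9)
})

test_that("a full-circle centerline closes on itself", {
  spec <- smallPhantomSpec(arcFraction = 1, seed = 5)
  pts <- canalCenterline(spec, 1L, seed = 2)
  gap <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  expect_lt(gap, spec@tubeRadiusMm / 2)
})

test_that("centerlines are deterministic given a seed and error when the circle cannot fit", {
  spec <- smallPhantomSpec(seed = 9)
  expect_identical(canalCenterline(spec, 2L, seed = 4),
                   canalCenterline(spec, 2L, seed = 4))
  expect_error(canalCenterline(spec, 99L), "canalIndex")
  big <- smallPhantomSpec(canalDiameterMm = 500, seed = 1)
  expect_error(canalCenterline(big, 0L, seed = 1), "does not fit")
})

test_that("rasterization marks exactly the voxels within the tube radius", {
  # single point at a voxel center, radius 1, 1 mm spacing: 7-voxel ball
  ball <- rasterizeTube(matrix(c(3.5, 3.5, 3.5), 1), 1.0, c(7L, 7L, 7L))
  expect_equal(sum(ball), 7)
  expect_true(ball[4, 4, 4] && ball[3, 4, 4] && ball[5, 4, 4] &&
              ball[4, 3, 4] && ball[4, 5, 4] && ball[4, 4, 3] && ball[4, 4, 5])
  # radius below half the spacing with the point off every voxel center
  none <- rasterizeTube(matrix(c(3.0, 3.0, 3.0), 1), 0.3, c(6L, 6L, 6L))
  expect_equal(sum(none), 0)
  # straight 5-point axial segment, radius 0.5: exactly those 5 voxels
  seg <- cbind(d = (0:4) + 0.5, h = 2.5, w = 2.5)
  line <- rasterizeTube(seg, 0.5, c(8L, 6L, 6L))
  expect_equal(sum(line), 5)
  expect_true(all(line[1:5, 3, 3]))
  expect_error(rasterizeTube(matrix(numeric(0), 0, 3), 1, c(4L, 4L, 4L)), "empty")
})

test_that("rasterization agrees with a brute-force polyline distance check", {
  set.seed(21)
  pts <- cbind(runif(4, 2, 8), runif(4, 2, 8), runif(4, 2, 8))
  r <- 1.2
  shape <- c(10L, 10L, 10L)
  mask <- rasterizeTube(pts, r, shape)
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    d <- oracle_point_polyline_dist(c(i, j, k) - 0.5, pts)
    expect_identical(unname(mask[i, j, k]), d <= r)
  }
})

test_that("phantom generation is seed-deterministic and respects empty specs", {
  spec <- smallPhantomSpec(seed = 13)
  v1 <- generatePhantom(spec)
  v2 <- generatePhantom(spec)
  expect_identical(intensities(v1), intensities(v2))
  expect_identical(labels3d(v1), labels3d(v2))
  quiet <- smallPhantomSpec(seed = 13, noiseSigma = 0)
  expect_identical(intensities(generatePhantom(quiet)),
                   intensities(generatePhantom(quiet)))
  empty <- smallPhantomSpec(nCanals = 0L, noiseSigma = 0, seed = 2)
  ev <- generatePhantom(empty)
  expect_equal(sum(labels3d(ev)), 0)
  expect_true(all(intensities(ev) == empty@intensityBackground))
})

test_that("phantom labels stay rare and remain brighter than background", {
  fracs <- vapply(1:20, function(s) {
    v <- generatePhantom(smallPhantomSpec(seed = s))
    mean(labels3d(v))
  }, numeric(1))
  expect_true(all(fracs < 0.01))
  expect_true(all(fracs > 0))
  spec <- smallPhantomSpec(seed = 30)
  v <- generatePhantom(spec)
  lab <- labels3d(v) != 0
  shellish <- intensities(v)[lab]
  bg <- intensities(v)[!lab]
  expect_gte(abs(mean(shellish) - mean(bg)), 3 * spec@noiseSigma)
})

test_that("every labeled voxel lies within the tube radius of a centerline", {
  spec <- smallPhantomSpec(seed = 17, nCanals = 1L, bilateral = FALSE)
  v <- generatePhantom(spec)
  # regenerate the centerline exactly as the generator drew it
  set.seed(spec@seed)
  cl <- canalCenterline(spec, 0L)
  idx <- which(labels3d(v) != 0, arr.ind = TRUE)
  dmax <- max(apply(idx, 1, function(ix)
    oracle_point_polyline_dist((ix - 0.5) * spec@spacingMm, cl)))
  expect_lte(dmax, spec@tubeRadiusMm + 1e-9)
})

test_that("dataset splits have the configured sizes and derive disjoint seeds", {
  spec <- smallPhantomSpec()
  ds <- generateDataset(spec, 3, 2, 1, seed = 77)
  expect_length(ds$train, 3)
  expect_length(ds$val, 2)
  expect_length(ds$test, 1)
  only_test <- generateDataset(spec, 0, 0, 1, seed = 5)
  expect_length(only_test$train, 0)
  expect_length(only_test$test, 1)
  ds2 <- generateDataset(spec, 3, 2, 1, seed = 77)
  expect_identical(intensities(ds$train[[1]]), intensities(ds2$train[[1]]))
  expect_identical(intensities(ds$test[[1]]), intensities(ds2$test[[1]]))
  # volumes are not shared between splits
  expect_false(identical(labels3d(ds$train[[1]]), labels3d(ds$val[[1]])))
})
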