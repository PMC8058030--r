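test_that("resampling is exact on identical grids and preserves constants", {
  set.seed(1)
  v <- imageVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(2, 2, 2))
  expect_identical(voxels(resampleTo(v, v)), voxels(v))

  const <- imageVolume(array(100, c(16, 16, 8)), c(1, 1, 1))
  coarse <- imageVolume(array(0, c(8, 8, 4)), c(2, 2, 2), origin = c(0.5, 0.5, 0.5))
  out <- resampleTo(const, coarse)
  expect_true(all(voxels(out) == 100))
})

test_that("trilinear resampling interpolates linearly between voxel centres", {
  a <- array(0, c(2, 1, 1)); a[2, 1, 1] <- 10
  moving <- imageVolume(a, c(2, 1, 1))
  target <- imageVolume(array(0, c(3, 1, 1)), c(1, 1, 1))
  expect_equal(voxels(resampleTo(moving, target))[, 1, 1], c(0, 5, 10))
})

test_that("out-of-field voxels get inert fill values and masks use nearest", {
  moving <- imageVolume(array(200, c(4, 4, 4)), c(1, 1, 1))
  wide <- imageVolume(array(0, c(10, 4, 4)), c(1, 1, 1), origin = c(-3, 0, 0))
  out <- resampleTo(moving, wide)
  expect_true(all(voxels(out)[1:2, , ] == -1000))   # HU fill
  doseMoving <- imageVolume(array(2, c(4, 4, 4)), c(1, 1, 1), unit = "Gy")
  expect_true(all(voxels(resampleTo(doseMoving, wide))[1:2, , ] == 0))

  m <- binaryMask(array(TRUE, c(4, 4, 4)), c(1, 1, 1), label = "ptv")
  rm <- resampleTo(m, wide)
  expect_s4_class(rm, "BinaryMask")
  expect_false(any(voxels(rm)[1:2, , ]))
})

test_that("non-overlapping extents are rejected with both bounding boxes named", {
  a <- imageVolume(array(0, c(4, 4, 4)), c(1, 1, 1), origin = c(0, 0, 0))
  b <- imageVolume(array(0, c(4, 4, 4)), c(1, 1, 1), origin = c(100, 0, 0))
  expect_error(resampleTo(a, b), "extents do not overlap.*100")
})

test_that("HU to RED conversion follows the calibration curve with clamping", {
  cv <- defaultCalibrationCurve()
  expect_equal(huToRed(0, cv), 1.0)       # water anchor
  expect_equal(huToRed(-1000, cv), 0.0)   # curve endpoint
  expect_equal(huToRed(-500, cv), 0.5)    # midpoint of first segment
  expect_equal(huToRed(-2000, cv), 0.0)   # clamped below
  expect_equal(huToRed(5000, cv), 2.5)    # clamped above

  vol <- imageVolume(array(c(-1000, -500, 0, 1000), c(4, 1, 1)), c(1, 1, 1))
  red <- huToRed(vol, cv)
  expect_equal(as.vector(voxels(red)), c(0, 0.5, 1, 1.55))
  expect_identical(red@unit, "RED")
})

test_that("hu_to_red is monotone for any valid curve", {
  set.seed(42)
  for (rep in 1:20) {
    below <- sort(sample(-1200:-1, 3))
    above <- sort(sample(1:3000, 3))
    hu <- c(below, 0, above)
    red <- c(sort(runif(3, 0, 1)), 1, 1 + sort(runif(3, 0, 1.5)))
    cv <- calibrationCurve(hu, red)
    x <- sort(runif(50, -1500, 3500))
    y <- huToRed(x, cv)
    expect_true(all(diff(y) >= -1e-12))
  }
})

test_that("invalid calibration curves are rejected", {
  expect_error(calibrationCurve(c(0, 0), c(1, 1)), "increasing")
  expect_error(calibrationCurve(c(-1000, 0), c(1, 0.5)), "non-decreasing")
  expect_error(calibrationCurve(c(-1000, 500), c(0, 1)), "water anchor")
})

test_that("body contour extraction keeps the largest component and fills cavities", {
  p <- boxPhantom()
  hu <- voxels(p$vol)
  hu[9:11, 9:11, 3] <- -900                 # internal air pocket
  hu[2, 2, 1] <- 0                          # small disjoint speck (9x smaller impossible: single voxel)
  body <- extractBodyContour(imageVolume(hu, c(1, 1, 1)))
  expect_equal(sum(voxels(body)), 600)      # 10 x 10 x 6, pocket filled, speck dropped
  expect_true(all(voxels(body)[9:11, 9:11, 3]))

  # only the larger of two disjoint objects is retained
  hu2 <- array(-1000, c(30, 10, 4))
  hu2[2:21, 3:8, ] <- 0                     # large block
  hu2[25:26, 4:5, 1] <- 0                   # 10x+ smaller block
  body2 <- extractBodyContour(imageVolume(hu2, c(1, 1, 1)))
  expect_equal(sum(voxels(body2)), 20 * 6 * 4)
  expect_false(any(voxels(body2)[25:26, , ]))

  expect_error(extractBodyContour(imageVolume(array(-1000, c(4, 4, 4)), c(1, 1, 1))),
               "no body found")
})

test_that("body contour is invariant to isolated noise specks outside the body", {
  p <- boxPhantom()
  ref <- extractBodyContour(p$vol)
  set.seed(7)
  hu <- voxels(p$vol)
  for (s in 1:12) {
    i <- sample(c(1:4, 17:20), 1); j <- sample(1:20, 1); k <- sample(1:6, 1)
    hu[i, j, k] <- 500
  }
  noisy <- extractBodyContour(imageVolume(hu, c(1, 1, 1)))
  expect_identical(voxels(noisy), voxels(ref))
})

test_that("NIfTI round trip preserves values, spacing and origin", {
  set.seed(3)
  v <- imageVolume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), c(1.5, 2, 3),
                   origin = c(-10, 5, 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(v, path)
  v2 <- readVolume(path)
  expect_equal(voxels(v2), voxels(v), tolerance = 1e-6)
  expect_equal(spacing(v2), spacing(v))
  expect_equal(origin(v2), origin(v))

  m <- binaryMask(voxels(v) > 0, c(1.5, 2, 3), origin = c(-10, 5, 2), label = "x")
  mpath <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(m, mpath)
  expect_identical(voxels(readMask(mpath, "x")), voxels(m))
})

test_that("calibration curve CSV round trips", {
  cv <- defaultCalibrationCurve()
  path <- withr::local_tempfile(fileext = ".csv")
  writeCalibrationCurve(cv, path)
  cv2 <- readCalibrationCurve(path)
  expect_equal(cv2@hu, cv@hu)
  expect_equal(cv2@red, cv@red)
})
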