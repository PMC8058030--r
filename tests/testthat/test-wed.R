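test_that("WED of a uniform water disk equals its radius within quadrature", {
  p <- diskPhantom(radiusMm = 50, spacingMm = 1)
  prof <- wedSlice(p$vol, p$body, 2, nDirections = 360, stepMm = 1)
  expect_true(all(abs(prof@wed - 50) <= 1))
  # halving the step halves the worst-case bound
  prof2 <- wedSlice(p$vol, p$body, 2, nDirections = 360, stepMm = 0.5)
  expect_true(all(abs(prof2@wed - 50) <= 0.5))
})

test_that("WED scales linearly with electron density", {
  # HU -500 maps to RED 0.5 on the default curve
  p <- diskPhantom(radiusMm = 50, spacingMm = 1, insideHu = -500)
  prof <- wedSlice(p$vol, p$body, 2, nDirections = 180, stepMm = 0.5)
  expect_true(all(abs(prof@wed - 25) <= 1))
})

test_that("WED integrates piecewise-constant density per direction", {
  # water in the anterior half, RED 1.5 material in the posterior half
  cv <- calibrationCurve(c(-1000, 0, 1000), c(0, 1, 1.5))
  p <- diskPhantom(radiusMm = 40, spacingMm = 1)
  hu <- voxels(p$vol)
  n <- dim(hu)[1]; cx <- (n + 1) / 2
  post <- matrix(rep(seq_len(n) > cx, each = n), n)   # posterior rows (y > centre)
  for (k in 1:3) {
    sl <- hu[, , k]
    sl[p$disk & post] <- 1000
    hu[, , k] <- sl
  }
  vol <- imageVolume(hu, spacing(p$vol))
  prof <- wedSlice(vol, p$body, 2, nDirections = 360, stepMm = 0.5,
                   curve = cv)
  ant <- prof@angles > 340 | prof@angles < 20         # pure water directions
  pos <- prof@angles > 160 & prof@angles < 200        # pure dense directions
  expect_true(all(abs(prof@wed[ant] - 40) <= 1.5))
  expect_true(all(abs(prof@wed[pos] - 60) <= 1.5))
})

test_that("WED is invariant under in-plane translation of the slice", {
  p <- diskPhantom(radiusMm = 30, spacingMm = 2, n = 64)
  prof <- wedSlice(p$vol, p$body, 2, nDirections = 90)
  shift <- c(5L, -3L)
  hu <- array(-1000, dim(voxels(p$vol)))
  bd <- array(FALSE, dim(hu))
  hu[(1 + shift[1]):64, 1:(64 + shift[2]), ] <-
    voxels(p$vol)[1:(64 - shift[1]), (1 - shift[2]):64, ]
  bd[(1 + shift[1]):64, 1:(64 + shift[2]), ] <-
    voxels(p$body)[1:(64 - shift[1]), (1 - shift[2]):64, ]
  prof2 <- wedSlice(imageVolume(hu, spacing(p$vol)),
                    binaryMask(bd, spacing(p$vol), label = "body"),
                    2, nDirections = 90)
  expect_equal(prof2@wed, prof@wed, tolerance = 1e-9)
})

test_that("WED differences report per-direction and summary statistics", {
  p <- diskPhantom(radiusMm = 30, spacingMm = 2, n = 64)
  prof <- wedSlice(p$vol, p$body, 2, nDirections = 100)
  d0 <- wedDifference(prof, prof)
  expect_true(all(d0$table$diff_mm == 0))
  expect_equal(d0$mean, 0); expect_equal(d0$sd, 0)

  up <- new("WEDProfile", region = prof@region, sliceIndex = prof@sliceIndex,
            center = prof@center, angles = prof@angles, wed = prof@wed + 1)
  d1 <- wedDifference(prof, up)
  expect_equal(d1$mean, 1); expect_equal(d1$sd, 0)

  one <- prof@wed; one[17] <- one[17] + 10
  pOne <- new("WEDProfile", region = prof@region, sliceIndex = prof@sliceIndex,
              center = prof@center, angles = prof@angles, wed = one)
  expect_equal(wedDifference(prof, pOne)$mean, 10 / 100)

  other <- new("WEDProfile", region = "elsewhere", sliceIndex = prof@sliceIndex,
               center = prof@center, angles = prof@angles, wed = prof@wed)
  expect_error(wedDifference(prof, other), "different regions")
  coarse <- wedSlice(p$vol, p$body, 2, nDirections = 50)
  expect_error(wedDifference(prof, coarse), "angle grids")
})

test_that("a concave slice with its centroid outside the body is rejected", {
  d <- c(40, 40, 1)
  hu <- array(-1000, d)
  body <- array(FALSE, d)
  # C-shape: ring with a bite taken out, centroid in the hollow
  cx <- 20.5
  x <- (seq_len(40) - cx)
  X <- matrix(rep(x, times = 40), 40); Y <- matrix(rep(x, each = 40), 40)
  ring <- X^2 + Y^2 <= 18^2 & X^2 + Y^2 >= 12^2 & !(Y < 0 & abs(X) < 6)
  body[, , 1] <- ring
  hu[, , 1][ring] <- 0
  expect_error(wedSlice(imageVolume(hu, c(1, 1, 1)),
                        binaryMask(body, c(1, 1, 1), label = "body"), 1,
                        nDirections = 36),
               "centre|center")
})

test_that("default direction count covers the full circle uniformly", {
  p <- diskPhantom(radiusMm = 20, spacingMm = 2, n = 32)
  prof <- wedSlice(p$vol, p$body, 1, nDirections = 8)
  expect_equal(prof@angles, seq(0, 315, by = 45))
})
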