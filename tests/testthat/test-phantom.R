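test_that("the phantom is deterministic under its seed", {
  a <- generatePhantom(smallPhantomSpec(seed = 42))
  b <- generatePhantom(smallPhantomSpec(seed = 42))
  expect_identical(voxels(a$ct), voxels(b$ct))
  expect_identical(voxels(a$masks$ptv_t), voxels(b$masks$ptv_t))
  c <- generatePhantom(smallPhantomSpec(seed = 43))
  expect_false(identical(voxels(a$ct), voxels(c$ct)))
})

test_that("a noiseless phantom segments exactly into its truth masks", {
  spec <- smallPhantomSpec(seed = 2,
                           huSd = c(background = 0, soft = 0, bone = 0, air = 0))
  ph <- generatePhantom(spec)
  body <- extractBodyContour(ph$ct)
  expect_identical(voxels(body), voxels(ph$truth$body))
  seg <- segmentTissues(ph$ct, body)
  for (cl in c("bone", "soft", "air"))
    expect_equal(diceCoefficient(slot(seg, cl), ph$truth[[cl]]), 1.0)
})

test_that("at default noise levels segmentation still recovers the truth", {
  ph <- generatePhantom(smallPhantomSpec(seed = 3))
  body <- extractBodyContour(ph$ct)
  seg <- segmentTissues(ph$ct, body)
  expect_gte(diceCoefficient(seg@bone, ph$truth$bone), 0.95)
  expect_gte(diceCoefficient(seg@air, ph$truth$air), 0.95)
  expect_gte(diceCoefficient(body, ph$truth$body), 0.99)
})

test_that("the zero perturbation returns the reference bitwise", {
  ph <- generatePhantom(smallPhantomSpec(seed = 5))
  sct <- perturbToSct(ph$ct, ph$truth, zeroPerturbation())
  expect_identical(voxels(sct), voxels(ph$ct))
})

test_that("noise-free per-tissue biases are recovered exactly by the mean error", {
  ph <- generatePhantom(smallPhantomSpec(seed = 6))
  spec <- perturbationSpec(biasHu = c(bone = -62, air = 107, soft = -1),
                           noiseSdHu = c(bone = 0, air = 0, soft = 0))
  sct <- perturbToSct(ph$ct, ph$truth, spec)
  expect_equal(meanErrors(ph$ct, sct, ph$truth$bone)$me_hu, -62)
  expect_equal(meanErrors(ph$ct, sct, ph$truth$air)$me_hu, 107)
  expect_equal(meanErrors(ph$ct, sct, ph$truth$soft)$me_hu, -1)
})

test_that("perturbation with the same seed is reproducible", {
  ph <- generatePhantom(smallPhantomSpec(seed = 7))
  p <- perturbationSpec(seed = 9)
  expect_identical(voxels(perturbToSct(ph$ct, ph$truth, p)),
                   voxels(perturbToSct(ph$ct, ph$truth, p)))
})

test_that("contour dilation followed by harmonization restores the interior", {
  ph <- generatePhantom(smallPhantomSpec(seed = 8))
  spec <- perturbationSpec(biasHu = c(bone = 0, air = 0, soft = 0),
                           noiseSdHu = c(bone = 0, air = 0, soft = 0),
                           contourMm = 5)
  sct <- perturbToSct(ph$ct, ph$truth, spec)
  expect_false(identical(voxels(sct), voxels(ph$ct)))
  bodyCand <- extractBodyContour(sct)
  h <- harmonizeBody(sct, bodyCand, ph$truth$body)
  inside <- voxels(ph$truth$body)
  expect_identical(voxels(h)[inside], voxels(ph$ct)[inside])
})

test_that("toy dose decays with depth and responds to upstream density", {
  # uniform water block, single beam entering at x = 1
  d <- c(40, 20, 8)
  hu <- array(0, d)
  vol <- imageVolume(hu, c(2, 2, 2))
  tp <- c(40, 20, 8)                 # physical centre-ish target
  beams <- toyBeamSpec(nBeams = 1, kernelSdMm = 0)
  res <- toyDose(vol, targetPoint = tp, beams = beams)
  profile <- voxels(res$dose)[, 10, 4]
  expect_true(all(diff(profile) < 0))          # monotone exponential decay

  # identical inputs give identical dose and a perfect gamma
  res2 <- toyDose(vol, targetPoint = tp, beams = beams)
  expect_identical(voxels(res$dose), voxels(res2$dose))

  # a dense slab upstream of the target lowers the target dose
  hu2 <- hu; hu2[5:8, , ] <- 200
  res3 <- toyDose(imageVolume(hu2, c(2, 2, 2)), targetPoint = tp,
                  beams = beams, scale = res$scale)
  tIdx <- round((tp - origin(res$dose)) / spacing(res$dose) + 1)
  expect_lt(voxels(res3$dose)[tIdx[1], tIdx[2], tIdx[3]],
            voxels(res$dose)[tIdx[1], tIdx[2], tIdx[3]])
})

test_that("the dose engine is linear in the prescription and normalizes the target", {
  ph <- generatePhantom(smallPhantomSpec(seed = 9))
  tp <- maskCentroid(ph$masks$ptv_t)
  r1 <- toyDose(ph$ct, targetPoint = tp, beams = toyBeamSpec(prescriptionGy = 68),
                body = ph$masks$body)
  tIdx <- round((tp - origin(r1$dose)) / spacing(r1$dose) + 1)
  expect_equal(voxels(r1$dose)[tIdx[1], tIdx[2], tIdx[3]], 68)
  expect_true(all(voxels(r1$dose) >= 0))
  r2 <- toyDose(ph$ct, targetPoint = tp, beams = toyBeamSpec(prescriptionGy = 34),
                body = ph$masks$body)
  expect_equal(voxels(r2$dose) * 2, voxels(r1$dose), tolerance = 1e-12)

  expect_error(toyDose(ph$ct, targetPoint = c(1e4, 0, 0), body = ph$masks$body),
               "outside")
})

test_that("more beams deposit more dose at a fixed calibration", {
  d <- c(24, 24, 6)
  vol <- imageVolume(array(0, d), c(4, 4, 4))
  tp <- c(46, 46, 10)
  one <- toyDose(vol, targetPoint = tp, beams = toyBeamSpec(nBeams = 1), scale = 1)
  four <- toyDose(vol, targetPoint = tp, beams = toyBeamSpec(nBeams = 4), scale = 1)
  tIdx <- round((tp - origin(one$dose)) / spacing(one$dose) + 1)
  expect_gt(voxels(four$dose)[tIdx[1], tIdx[2], tIdx[3]],
            voxels(one$dose)[tIdx[1], tIdx[2], tIdx[3]])
})
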