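makeBodyPair <- function() {
  d <- c(24, 24, 6)
  hu <- array(-1000, d)
  hu[6:19, 6:19, ] <- 50
  bodyArr <- array(FALSE, d); bodyArr[6:19, 6:19, ] <- TRUE
  list(hu = hu, body = bodyArr, d = d)
}

test_that("body harmonization implements the outside-air / connected-water rules", {
  s <- makeBodyPair()
  hu <- s$hu
  hu[10:12, 10:12, 3] <- -800                 # enclosed interior air
  hu[6, 8:12, ] <- -800                       # air layer touching the contour
  refB <- binaryMask(s$body, c(1, 1, 1), label = "body")

  # identity: same body, no contour-connected air
  huId <- s$hu
  hId <- harmonizeBody(imageVolume(huId, c(1, 1, 1)), refB, refB)
  expect_identical(voxels(hId), huId)

  # candidate one voxel wider: shell set to air
  candArr <- s$body; candArr[5, 6:19, ] <- TRUE
  candB <- binaryMask(candArr, c(1, 1, 1), label = "body")
  hu2 <- hu; hu2[5, 6:19, ] <- 40
  h <- harmonizeBody(imageVolume(hu2, c(1, 1, 1)), candB, refB)
  expect_true(all(voxels(h)[5, 6:19, ] == -1000))
  # contour-connected air -> water, enclosed air preserved
  expect_true(all(voxels(h)[6, 8:12, ] == 0))
  expect_true(all(voxels(h)[10:12, 10:12, 3] == -800))
})

test_that("harmonization never alters deep interior tissue", {
  set.seed(31)
  s <- makeBodyPair()
  hu <- s$hu
  hu[8:17, 8:17, 2:5] <- rnorm(10 * 10 * 4, 60, 40)  # interior, all above airMax
  refB <- binaryMask(s$body, c(1, 1, 1), label = "body")
  candArr <- s$body; candArr[5, 6:19, ] <- TRUE
  candB <- binaryMask(candArr, c(1, 1, 1), label = "body")
  h <- harmonizeBody(imageVolume(hu, c(1, 1, 1)), candB, refB)
  expect_identical(voxels(h)[8:17, 8:17, 2:5], hu[8:17, 8:17, 2:5])
})

test_that("skin cropping removes the expected surface layers", {
  d <- c(24, 24, 8)
  bodyArr <- array(FALSE, d); bodyArr[3:22, 3:22, ] <- TRUE
  body <- binaryMask(bodyArr, c(1, 1, 1), label = "body")
  # slab PTV touching the body surface at x = 3
  ptvArr <- array(FALSE, d); ptvArr[3:12, 10:14, 4:5] <- TRUE
  ptv <- binaryMask(ptvArr, c(1, 1, 1), label = "PTV_T")

  expect_identical(voxels(cropPtvFromSkin(ptv, body, 0)), voxels(ptv))

  crop <- cropPtvFromSkin(ptv, body, 4)
  # layers x = 3..6 are within 4 mm of the surface voxel layer at x = 3
  expect_false(any(voxels(crop)[3:6, , ]))
  expect_true(all(voxels(crop)[7:12, 10:14, 4:5]))

  deep <- binaryMask(array(FALSE, d), c(1, 1, 1), label = "PTV_T")
  deepArr <- voxels(deep); deepArr[12:13, 12:13, 4] <- TRUE
  deep <- binaryMask(deepArr, c(1, 1, 1), label = "PTV_T")
  expect_identical(voxels(cropPtvFromSkin(deep, body, 4)), voxels(deep))

  thin <- binaryMask(ptvArr & FALSE, c(1, 1, 1), label = "PTV_T")
  thinArr <- voxels(thin); thinArr[3, 10, 4] <- TRUE
  thin <- binaryMask(thinArr, c(1, 1, 1), label = "PTV_T")
  expect_error(cropPtvFromSkin(thin, body, 4), "entirely within")
})

test_that("DVH summary matches closed forms and the sorting oracle", {
  d <- c(10, 10, 1)
  mask <- binaryMask(array(TRUE, d), c(1, 1, 1), label = "s")
  uni <- imageVolume(array(60, d), c(1, 1, 1), unit = "Gy")
  s <- dvhSummary(uni, mask)
  expect_equal(dMean(s), 60); expect_equal(dNearMax(s), 60)
  expect_equal(dNearMin(s), 60)
  expect_equal(s@volumeCc, 100 / 1000)

  doses <- sample(1:100)
  grid <- imageVolume(array(as.numeric(doses), d), c(1, 1, 1), unit = "Gy")
  s2 <- dvhSummary(grid, mask)
  expect_equal(dMean(s2), 50.5)
  expect_equal(dNearMax(s2), bruteDvhPoint(doses, 2))
  expect_equal(dNearMin(s2), bruteDvhPoint(doses, 98))

  # linearity under dose scaling
  s3 <- dvhSummary(imageVolume(2 * voxels(grid), c(1, 1, 1), unit = "Gy"), mask)
  expect_equal(dMean(s3), 2 * dMean(s2))
  expect_equal(dNearMax(s3), 2 * dNearMax(s2))
  expect_equal(dNearMin(s3), 2 * dNearMin(s2))

  expect_error(dvhSummary(uni, binaryMask(array(FALSE, d), c(1, 1, 1),
                                          label = "e")), "empty mask")
})

test_that("DVH ordering d98 <= dmean <= d2 holds on random dose grids", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(20:200, 1)
    doses <- runif(n, 0, 80)
    d <- c(n, 1, 1)
    s <- dvhSummary(imageVolume(array(doses, d), c(1, 1, 1), unit = "Gy"),
                    binaryMask(array(TRUE, d), c(1, 1, 1), label = "s"))
    expect_lte(dNearMin(s), dMean(s) + 1e-9)
    expect_lte(dMean(s), dNearMax(s) + 1e-9)
  }
})

comparisonFixture <- function(scale = 1, oarLevel = 30) {
  d <- c(20, 20, 8)
  doseArr <- array(5, d)
  doseArr[5:16, 5:16, ] <- 70
  doseArr[3:4, 3:4, 1:2] <- oarLevel
  ref <- imageVolume(doseArr, c(2, 2, 2), unit = "Gy")
  cand <- imageVolume(doseArr * scale, c(2, 2, 2), unit = "Gy")
  mk <- function(idx, label) {
    a <- array(FALSE, d); a[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    binaryMask(a, c(2, 2, 2), label = label)
  }
  structures <- list(body = mk(list(2:19, 2:19, 1:8), "body"),
                     ptv_t = mk(list(8:13, 8:13, 3:6), "PTV_T"),
                     oar = mk(list(3:4, 3:4, 1:2), "OAR"))
  roles <- c(body = "body", ptv_t = "ptv_t", oar = "parallel_oar")
  list(ref = ref, cand = cand, structures = structures, roles = roles)
}

test_that("plan comparison yields zero for identity and the scaling for scaled plans", {
  f <- comparisonFixture(scale = 1)
  tab <- comparePlans(f$ref, f$cand, f$structures, f$roles,
                      evaluationRules(prescriptionGy = 70))
  expect_true(all(tab$rel_diff_pct[tab$included] == 0))
  expect_true(all(tab$abs_diff_gy[tab$included] == 0))

  f2 <- comparisonFixture(scale = 1.01)
  tab2 <- comparePlans(f2$ref, f2$cand, f2$structures, f2$roles,
                       evaluationRules(prescriptionGy = 70))
  expect_equal(tab2$rel_diff_pct[tab2$included], rep(1, sum(tab2$included)),
               tolerance = 1e-9)
})

test_that("the OAR gate excludes organs below 10% of the prescription", {
  rules <- evaluationRules(prescriptionGy = 68)
  fLow <- comparisonFixture(oarLevel = 6.7)
  tabLow <- comparePlans(fLow$ref, fLow$cand, fLow$structures, fLow$roles, rules)
  oarLow <- tabLow[tabLow$structure == "oar", ]
  expect_false(any(oarLow$included))
  expect_match(oarLow$reason[1], "below 6.8 Gy")

  fHigh <- comparisonFixture(oarLevel = 6.9)
  tabHigh <- comparePlans(fHigh$ref, fHigh$cand, fHigh$structures, fHigh$roles, rules)
  expect_true(all(tabHigh[tabHigh$structure == "oar", "included"]))
})

test_that("roles select the evaluated DVH parameters", {
  f <- comparisonFixture()
  roles <- c(body = "body", ptv_t = "ptv_n", oar = "serial_oar")
  tab <- comparePlans(f$ref, f$cand, f$structures, roles,
                      evaluationRules(prescriptionGy = 70))
  expect_equal(tab$parameter[tab$structure == "ptv_t"], "D_98")
  expect_equal(tab$parameter[tab$structure == "oar"], "D_2")
  expect_setequal(tab$parameter[tab$structure == "body"], c("D_mean", "D_2"))
})

test_that("per-structure failures are recorded without aborting the run", {
  f <- comparisonFixture()
  bad <- binaryMask(array(FALSE, c(3, 3, 3)), c(2, 2, 2), label = "broken")
  structures <- c(f$structures, list(broken = bad))
  roles <- c(f$roles, broken = "parallel_oar")
  tab <- comparePlans(f$ref, f$cand, structures, roles,
                      evaluationRules(prescriptionGy = 70))
  brokenRow <- tab[tab$structure == "broken", ]
  expect_false(brokenRow$included)
  expect_true(is.na(brokenRow$parameter))
  expect_true(all(tab$included[tab$structure == "ptv_t"]))
})

test_that("swapping reference and candidate flips the absolute difference sign", {
  f <- comparisonFixture(scale = 1.02)
  rules <- evaluationRules(prescriptionGy = 70)
  fwd <- comparePlans(f$ref, f$cand, f$structures, f$roles, rules)
  rev <- comparePlans(f$cand, f$ref, f$structures, f$roles, rules)
  expect_equal(rev$abs_diff_gy, -fwd$abs_diff_gy)
})
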