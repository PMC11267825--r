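test_that("the global signal is the masked pixel sum", {
  fr <- array(1, dim = c(3, 10, 10))
  mask <- matrix(FALSE, 10, 10); mask[1:10, 1:10] <- TRUE
  eit <- eitSequence(fr, 47, mask)
  expect_equal(globalSignal(eit), rep(100, 3))
  mask2 <- mask; mask2[, 6:10] <- FALSE
  expect_equal(globalSignal(eitSequence(fr, 47, mask2)), rep(50, 3))
})

test_that("landmarks pick ramp endpoints and break ties at the earliest frame", {
  sync <- list(tSyncAirway = 0, frameSync = 1L, frameRate = 10)
  ramp <- c(rep(5, 10), 5 + seq_len(20), rep(25, 10))
  lm <- breathLandmarksEIT(ramp, tInspStart = 1.0, tExpEnd = 3.8, sync)
  expect_equal(lm$inspStartFrame, 6)   # earliest minimum in the window
  expect_equal(lm$inspEndFrame, 30)    # first frame reaching the maximum
  flat <- rep(1, 40)
  lmF <- breathLandmarksEIT(flat, tInspStart = 1.0, tExpEnd = 3.8, sync)
  expect_equal(lmF$inspStartFrame, 6)  # first frame of the window
})

test_that("tiv and eeli read off the global curve, flagging negative TIV", {
  sig <- c(2000, 2500, 3500)
  ge <- tivEeli(sig, list(inspStartFrame = 1, inspEndFrame = 3))
  expect_equal(ge$eeli, 2000)
  expect_equal(ge$tiv, 1500)
  expect_false(ge$incomplete)
  ge2 <- tivEeli(rev(sig), list(inspStartFrame = 1, inspEndFrame = 3))
  expect_true(ge2$incomplete)
})

test_that("the tidal image is the masked frame difference, summing to TIV", {
  set.seed(1)
  fr <- array(runif(2 * 8 * 8), dim = c(2, 8, 8))
  mask <- matrix(TRUE, 8, 8)
  eit <- eitSequence(fr, 47, mask)
  img <- tidalImage(eit, list(inspStartFrame = 1, inspEndFrame = 2))
  expect_equal(img@dz, fr[2, , ] - fr[1, , ])
  sig <- globalSignal(eit)
  expect_equal(sum(img@dz), sig[2] - sig[1], tolerance = 1e-12)
  eitSame <- eitSequence(fr[c(1, 1), , ], 47, mask)
  imgSame <- tidalImage(eitSame, list(inspStartFrame = 1, inspEndFrame = 2))
  expect_true(all(imgSame@dz == 0))
})

test_that("the centroid reproduces hand-computed cases", {
  # 4-row extent, all mass in the dorsal row -> centroid at 87.5%
  dz <- matrix(0, 4, 4); dz[4, ] <- 1
  expect_equal(centerOfVentilation(tidalImageOf(dz))$cov_vd, 87.5)
  # row weights (ventral->dorsal) 0,1,3,0 -> (1*37.5 + 3*62.5)/4 = 56.25
  dz2 <- matrix(0, 4, 4); dz2[2, ] <- 1 / 4; dz2[3, ] <- 3 / 4
  expect_equal(centerOfVentilation(tidalImageOf(dz2))$cov_vd, 56.25)
  # uniform ventilation -> 50% on both axes
  dz3 <- matrix(1, 6, 6)
  cov3 <- centerOfVentilation(tidalImageOf(dz3))
  expect_equal(cov3$cov_vd, 50)
  expect_equal(cov3$cov_rl, 50)
  # single-row extent maps to 50% rather than dividing by zero
  dz4 <- matrix(0, 5, 5); dz4[3, ] <- 1
  mask4 <- matrix(FALSE, 5, 5); mask4[3, ] <- TRUE
  expect_equal(centerOfVentilation(tidalImageOf(dz4, mask4))$cov_vd, 50)
})

test_that("centroid equals the brute-force pixel loop on random images", {
  set.seed(42)
  for (rep in 1:20) {
    img <- randomTidalImage()
    fast <- centerOfVentilation(img)
    slow <- bruteForceCov(img)
    expect_equal(fast$cov_vd, slow$cov_vd, tolerance = 1e-9)
    expect_equal(fast$cov_rl, slow$cov_rl, tolerance = 1e-9)
  }
})

test_that("silent spaces use a strict 10%-of-maximum threshold and the CoV split", {
  dz <- matrix(100, 10, 10)
  dz[1, 1] <- 9.9    # ventral corner: silent (strictly below 10)
  dz[10, 1] <- 10.1  # dorsal corner: not silent
  ss <- silentSpaces(tidalImageOf(dz), covVd = 50)
  expect_equal(ss$dss, 1)  # one silent pixel, ventral of the plane
  expect_equal(ss$nss, 0)
  # pixels dorsal to the plane count as NSS
  dz2 <- matrix(100, 10, 10); dz2[8:10, 1:2] <- 0
  ss2 <- silentSpaces(tidalImageOf(dz2), covVd = 50)
  expect_equal(ss2$nss, 6)
  expect_equal(ss2$dss, 0)
  # uniform ventilation has no silent space at all
  ssU <- silentSpaces(tidalImageOf(matrix(7, 6, 6)), covVd = 50)
  expect_equal(ssU$nss + ssU$dss, 0)
})

test_that("band fractions split the extent into four equal-width bands", {
  dz <- matrix(0, 8, 8); dz[1:2, ] <- 1  # all mass in the ventral quarter
  b <- regionalBands(tidalImageOf(dz))
  expect_equal(unlist(b), c(dz_v = 100, dz_cv = 0, dz_cd = 0, dz_d = 0))
  set.seed(7)
  img <- randomTidalImage()
  bb <- unlist(regionalBands(img))
  expect_equal(sum(bb), 100, tolerance = 0.01)
})

test_that("ventilation measures are scale invariant, TIV scales linearly", {
  set.seed(9)
  img <- randomTidalImage()
  img2 <- img; img2@dz <- img@dz * 3.7
  expect_equal(centerOfVentilation(img), centerOfVentilation(img2),
               tolerance = 1e-12)
  cov <- centerOfVentilation(img)$cov_vd
  expect_equal(silentSpaces(img, cov), silentSpaces(img2, cov))
  expect_equal(regionalBands(img), regionalBands(img2), tolerance = 1e-12)
  p1 <- breathEIT:::.pixelGeometry(img)
  p2 <- breathEIT:::.pixelGeometry(img2)
  expect_equal(sum(p2$dz), 3.7 * sum(p1$dz), tolerance = 1e-12)
})

test_that("shifting mass dorsally raises the centroid and the dorsal band", {
  dz <- matrix(0, 8, 8); dz[3:5, ] <- 1
  img1 <- tidalImageOf(dz)
  dz2 <- rbind(matrix(0, 1, 8), dz[-8, ])  # one row dorsal
  img2 <- tidalImageOf(dz2)
  expect_gt(centerOfVentilation(img2)$cov_vd,
            centerOfVentilation(img1)$cov_vd)
  expect_gte(regionalBands(img2)$dz_d, regionalBands(img1)$dz_d)
})

test_that("nss + dss equals an independent direct count of silent pixels", {
  set.seed(11)
  for (rep in 1:10) {
    img <- randomTidalImage()
    cov <- centerOfVentilation(img)$cov_vd
    ss <- silentSpaces(img, cov)
    dz <- pmax(img@dz[img@mask], 0)
    direct <- 100 * sum(dz < 0.1 * max(dz)) / sum(img@mask)
    expect_equal(ss$nss + ss$dss, direct, tolerance = 1e-9)
  }
})
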