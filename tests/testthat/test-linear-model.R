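# Quasi-linear prediction: Fourier filter, squared-pixel thresholding,
# prediction scoring, orientation power and masked-image OSI.

SFS3 <- c(1.5, 3, 6)

test_that("the SRF filter is normalized and shaped as specified", {
  R <- gaussianSRF(ORIS8, SFS3, 67.5, 3)
  flt <- buildSRFFilter(R, 64, 1 / 24, ORIS8, SFS3)
  expect_equal(flt@gain[1, 1], 0)  # DC excluded
  opt <- makeGrating(gratingStim(67.5, 3, 0), 64, 1 / 24)
  expect_equal(max(filterImage(opt, flt)), 1, tolerance = 0.01)
  # constant SRF -> flat gain over the characterized band
  fltC <- buildSRFFilter(matrix(1, 8, 3), 64, 1 / 24, ORIS8, SFS3)
  inband <- bubbleSTM:::fftPolarGrid(64, 1 / 24)$f
  g <- fltC@gain[inband >= 1.5 & inband <= 6]
  expect_lt(diff(range(g)), 1e-9)
  # delta SRF: peak gain sits at the two conjugate-symmetric bins of the
  # preferred grating, and the gain grid is conjugate-symmetric overall
  Rd <- matrix(0, 8, 3); Rd[4, 2] <- 1  # 67.5 deg, 3 cpd
  fltD <- buildSRFFilter(Rd, 64, 1 / 24, ORIS8, SFS3)
  opt2 <- makeGrating(gratingStim(67.5, 3, 0), 64, 1 / 24)
  pkBin <- arrayInd(which.max(Mod(stats::fft(opt2 - mean(opt2)))),
                    c(64, 64))
  expect_equal(fltD@gain[pkBin[1], pkBin[2]], max(fltD@gain))
  conj <- fltD@gain[c(1, 64:2), c(1, 64:2)]  # gain at (-u, -v)
  expect_equal(fltD@gain, conj)
  # passband vs stopband response ratio follows the gain ratio
  stopG <- makeGrating(gratingStim(157.5, 3, 0), 64, 1 / 24)
  expect_lt(max(filterImage(stopG, flt)), 0.05)
})

test_that("filterImage preserves phase, squares, and satisfies Parseval", {
  img <- generateBaseImage(64, 1, 1 / 24, seed = 21)
  px <- pixels(img)
  allpass <- new("FourierFilter", gain = matrix(1, 64, 64), size = 64,
                 degPerPx = 1 / 24, scale = 1)
  allpass@gain[1, 1] <- 0
  expect_equal(filterImage(px, allpass), (px - mean(px))^2,
               tolerance = 1e-10)
  zero <- new("FourierFilter", gain = matrix(0, 64, 64), size = 64,
              degPerPx = 1 / 24, scale = 1)
  expect_equal(filterImage(px, zero), matrix(0, 64, 64))
  flt <- buildSRFFilter(gaussianSRF(ORIS8, SFS3, 45, 3), 64, 1 / 24,
                        ORIS8, SFS3)
  out <- filterImage(px, flt)
  spectral <- sum((flt@gain * Mod(stats::fft(px - mean(px))))^2) / 64^2
  expect_equal(sum(out), spectral, tolerance = 1e-8)
})

test_that("predicted masks match the target area with deterministic ties", {
  img <- generateBaseImage(64, 1, 1 / 24, seed = 22)
  # area matching: exactly k pixels survive, and they are the k largest
  # values of the filtered squared raster
  flat <- matrix(1, 8, 3)
  pm <- predictMasks(img, flat, 150, 1 / 24, ORIS8, SFS3)
  expect_equal(sum(pm@excit), 150)
  flt <- buildSRFFilter(flat, 64, 1 / 24, ORIS8, SFS3)
  FE <- filterImage(pixels(img), flt)
  expect_gte(min(FE[pm@excit]), max(FE[!pm@excit]))
  expect_equal(pm@threshold, min(FE[pm@excit]), tolerance = 1e-12)
  # unity SRF everywhere -> 1 - SRF = 0 -> empty suppressive set
  expect_equal(sum(pm@suppr), 0)
  # optimal grating patch: excitatory pixels confined to the patch
  g <- makeGrating(gratingStim(45, 3, 0, innerDeg = 0.4, outerDeg = 0.6),
                   64, 1 / 24)
  ctrDist <- sqrt(outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+")) / 24
  pmG <- predictMasks(g, gaussianSRF(ORIS8, SFS3, 45, 3), 120, 1 / 24,
                      ORIS8, SFS3)
  expect_gt(mean(ctrDist[pmG@excit] <= 0.7), 0.95)
  expect_error(predictMasks(img, flat, 64 * 64 + 1, 1 / 24, ORIS8, SFS3),
               "targetArea")
})

test_that("prediction scoring matches hand-computed overlaps", {
  mkStm <- function(excitSel, supprSel = NULL) {
    lab <- matrix(0L, 64, 64); lab[excitSel] <- 1L
    w <- matrix(0, 64, 64); w[excitSel] <- 1
    if (!is.null(supprSel)) { lab[supprSel] <- -1L; w[supprSel] <- -1 }
    new("SpikeTriggeredMask", imageId = "a", weights = w, labels = lab,
        area = sum(lab != 0), centroid = c(1, 1), valid = TRUE,
        meta = list())
  }
  E <- matrix(FALSE, 64, 64); E[1:10, 1:10] <- TRUE        # 100 px
  P <- matrix(FALSE, 64, 64); P[1:10, 3:10] <- TRUE        # 80 px, 80 in E
  P2 <- matrix(FALSE, 64, 64); P2[1:8, 1:5] <- TRUE        # 40 in E
  pm <- new("PredictedMask", imageId = "a", excit = E, suppr = E,
            threshold = 1)
  self <- scorePrediction(pm, mkStm(E, NULL))
  expect_equal(self$overlapPct[1], 100)
  pm2 <- new("PredictedMask", imageId = "a", excit = P2,
             suppr = matrix(FALSE, 64, 64), threshold = 1)
  sc <- scorePrediction(pm2, mkStm(E))
  expect_equal(sc$overlapPct[1], 40)          # 40 / max(40, 100) * 100
  expect_equal(sc$sizeDiffPct[1], 60)
  expect_true(is.na(sc$overlapPct[2]))        # both suppressive sets empty
  D <- matrix(FALSE, 64, 64); D[40:49, 40:49] <- TRUE
  pmD <- new("PredictedMask", imageId = "a", excit = D,
             suppr = matrix(FALSE, 64, 64), threshold = 1)
  expect_equal(scorePrediction(pmD, mkStm(E))$overlapPct[1], 0)
})

test_that("orientation power peaks at the content orientation", {
  sel <- matrix(FALSE, 64, 64); sel[20:45, 20:45] <- TRUE
  g <- makeGrating(gratingStim(67.5, 3, 0), 64, 1 / 24)
  op <- orientationPower(g, sel, ORIS8)
  expect_equal(op$orientation[which.max(op$power)], 67.5)
  # rotating the image by 90 degrees shifts the curve by 90 degrees
  g90 <- t(g)[, 64:1]  # 90-degree rotation
  op90 <- orientationPower(g90, sel, ORIS8)
  expect_equal((op$orientation[which.max(op$power)] + 90) %% 180,
               op90$orientation[which.max(op90$power)])
  # isotropic noise: no orientation dominates strongly
  noise <- withr::with_seed(3, matrix(runif(64 * 64), 64, 64))
  opN <- orientationPower(noise, sel, ORIS8)
  expect_lt(max(opN$power) / mean(opN$power), 2)
  expect_error(orientationPower(g, matrix(FALSE, 64, 64), ORIS8),
               "empty")
})

test_that("masked-image OSI separates oriented from isotropic content", {
  mkStm <- function(sel) {
    lab <- matrix(0L, 64, 64); lab[sel] <- 1L
    w <- matrix(0, 64, 64); w[sel] <- 1
    new("SpikeTriggeredMask", imageId = "a", weights = w, labels = lab,
        area = sum(lab), centroid = c(32, 32), valid = TRUE,
        meta = list())
  }
  sel <- matrix(FALSE, 64, 64); sel[16:48, 16:48] <- TRUE
  g <- makeGrating(gratingStim(67.5, 3, 0), 64, 1 / 24)
  res <- imageMaskOSI(g, mkStm(sel), ORIS8, SFS3, degPerPxVal = 1 / 24)
  expect_equal(res$prefOri, 67.5)
  expect_gt(res$osi, 1)
  # isotropic noise: OSI far below the oriented case (the |dot|-based
  # pseudo-response floor keeps it away from exactly 0)
  noiseOsis <- vapply(4:6, function(s) {
    noise <- withr::with_seed(s, matrix(runif(64 * 64), 64, 64))
    imageMaskOSI(noise, mkStm(sel), ORIS8, SFS3,
                 degPerPxVal = 1 / 24)$osi
  }, numeric(1))
  expect_lt(mean(noiseOsis), 1)
  expect_lt(mean(noiseOsis), res$osi / 3)
  empty <- mkStm(matrix(FALSE, 64, 64))
  expect_error(imageMaskOSI(g, empty, ORIS8, SFS3,
                            degPerPxVal = 1 / 24), "excitatory")
})
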