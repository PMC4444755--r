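# Spike-triggered masks: frame responses, weighted averages, shuffle-null
# significance, metrics and similarity analysis.

test_that("frame responses use the half-open 50-150 ms window", {
  ses <- new("SessionLog",
             frames = data.frame(frame_id = 1:3,
                                 onset_ms = c(0, 240, 480),
                                 duration_ms = 240),
             spikes = c(60, 100, 149, 240 + 150, 480 + 50),
             maskCenters = list(), baseImages = list(),
             meta = list(type = "bubbles", size = 32, degPerPx = 1 / 16))
  r <- computeFrameResponses(ses)
  expect_equal(r$w, c(30, 0, 10))  # 3 spikes / 0.1 s; boundary excluded
  expect_error(computeFrameResponses(ses, window = c(0, 300)),
               "invalid-configuration")
})

test_that("rawSTM is an order-invariant weighted average", {
  withr::with_seed(4, {
    masks <- replicate(80, transparency(makeBubbleMask(32, 5, 3)),
                       simplify = FALSE)
  })
  w <- seq_len(80)
  map <- rawSTM(masks, w)
  # oracle: direct weighted average
  direct <- Reduce(`+`, Map(`*`, masks, w)) / sum(w)
  expect_equal(map, direct)
  perm <- rev(seq_len(80))
  expect_equal(rawSTM(masks[perm], w[perm]), map)
  expect_error(rawSTM(masks, numeric(80)), "empty-stm")
  expect_error(rawSTM(masks, w[-1]), "one response per mask")
})

test_that("shuffle significance recovers planted structure and degenerates sanely", {
  withr::with_seed(5, {
    masks <- replicate(400, transparency(makeBubbleMask(32, 5, 3)),
                       simplify = FALSE)
  })
  # response equals the transparency at one pixel
  p0 <- c(12, 20)  # row, col
  w <- 100 * vapply(masks, function(m) m[p0[1], p0[2]], numeric(1))
  stm <- computeSTM(masks, w, nShuffles = 300, seed = 6)
  expect_true(stm@valid)
  pk <- arrayInd(which.max(stmWeights(stm)), c(32, 32))
  expect_lt(sqrt(sum((pk - p0)^2)), 3)
  expect_true(all(stmWeights(stm)[stmLabels(stm) == 1] > 0))
  expect_equal(stm@area, sum(stmLabels(stm) != 0))
  # alpha = 1: every pixel significant
  stmAll <- computeSTM(masks, w, alpha = 1, nShuffles = 300, seed = 6)
  expect_equal(stmAll@area, 32 * 32)
  # scale equivariance: responses scaled by c > 0, same shuffles
  stm2 <- computeSTM(masks, 3.7 * w, nShuffles = 300, seed = 6)
  expect_identical(stmLabels(stm2), stmLabels(stm))
  expect_error(computeSTM(masks, w, nShuffles = 50), "shuffles")
  expect_error(computeSTM(masks[1:10], w[1:10], nShuffles = 300),
               "insufficient-data")
})

test_that("the shuffle null is calibrated on response-shuffled input", {
  withr::with_seed(7, {
    masks <- replicate(600, transparency(makeBubbleMask(32, 5, 3)),
                       simplify = FALSE)
    w <- rpois(600, 20)  # independent of the masks: true null
  })
  stm <- computeSTM(masks, w, alpha = 0.05, nShuffles = 400, seed = 8)
  rate <- stm@area / (32 * 32)
  expect_gt(rate, 0.05 * 0.3)
  expect_lt(rate, 0.05 * 2.5)
})

test_that("mask metrics report area fraction, centroid and CRF escape", {
  lab <- matrix(0L, 64, 64)
  lab[20:29, 20:29] <- 1L  # 100 excitatory pixels
  w <- matrix(0, 64, 64); w[lab == 1] <- 0.5
  stm <- new("SpikeTriggeredMask", imageId = "a", weights = w,
             labels = lab, area = 100,
             centroid = c(x = 24.5, y = 24.5), valid = TRUE,
             meta = list())
  mm <- maskMetrics(stm, 20 / 24, 1 / 24)  # CRF radius 20 px
  expect_equal(mm$areaPx, 100)
  expect_equal(mm$areaFractionOfCRF, 100 / (pi * 400))
  # square corners reach ~17.7 px from center: inside 20, outside 10
  expect_false(mm$crfOutsideFlag)
  expect_true(maskMetrics(stm, 10 / 24, 1 / 24)$crfOutsideFlag)
  empty <- new("SpikeTriggeredMask", imageId = "a",
               weights = matrix(0, 64, 64), labels = matrix(0L, 64, 64),
               area = 0, centroid = c(NA_real_, NA_real_), valid = FALSE,
               meta = list())
  me <- maskMetrics(empty, 20 / 24, 1 / 24)
  expect_equal(me$areaFractionOfCRF, 0)
  expect_true(all(is.na(me$centroid)))
})

test_that("similarity analysis is monotone and correlates with responses", {
  w <- matrix(0, 32, 32); w[10:20, 10:20] <- 1
  lab <- matrix(0L, 32, 32); lab[10:20, 10:20] <- 1L
  stm <- new("SpikeTriggeredMask", imageId = "a", weights = w,
             labels = lab, area = sum(lab), centroid = c(15, 15),
             valid = TRUE, meta = list())
  big <- matrix(0.8, 32, 32); small <- matrix(0.2, 32, 32)
  sim <- similarityAnalysis(stm, list(big, small), c(1, 1), q = 50)
  expect_gt(sim$similarity[1], sim$similarity[2])  # pointwise dominance
  zero <- new("SpikeTriggeredMask", imageId = "a",
              weights = matrix(0, 32, 32), labels = matrix(0L, 32, 32),
              area = 0, centroid = c(NA_real_, NA_real_), valid = FALSE,
              meta = list())
  expect_true(all(similarityAnalysis(zero, list(big, small),
                                     c(1, 1))$similarity == 0))
  # simulated template neuron: similarity predicts response
  img <- generateBaseImage(64, 1, 1 / 24, id = "a", seed = 3)
  n <- calibrateGain(templateNeuronFor(img, c(22, 40), threshold = 0),
                     img)
  ses <- simulateBubbleSession(n, img, 800, seed = 12)
  resp <- computeFrameResponses(ses)
  M <- bubbleSTM:::sessionMaskMatrix(ses)
  stmN <- computeSTM(M, resp$w, "a", nShuffles = 300, seed = 13)
  sa <- similarityAnalysis(stmN, M, resp$w, q = 90)
  expect_gt(cor(sa$similarity, resp$w, method = "spearman"), 0.3)
  expect_gt(sa$meanTopRate, mean(resp$w))
})

test_that("intermask comparison computes overlap and size differences", {
  mk <- function(sel) {
    lab <- matrix(0L, 32, 32); lab[sel] <- 1L
    w <- matrix(0, 32, 32); w[sel] <- 1
    new("SpikeTriggeredMask", imageId = "a", weights = w, labels = lab,
        area = sum(lab), centroid = c(1, 1), valid = TRUE, meta = list())
  }
  A <- matrix(FALSE, 32, 32); A[1:10, 1:20] <- TRUE   # 200 px
  B <- matrix(FALSE, 32, 32); B[1:10, 1:10] <- TRUE   # 100 px inside A
  C <- matrix(FALSE, 32, 32); C[20:29, 20:29] <- TRUE # 100 px disjoint
  same <- intermaskComparison(list(mk(A), mk(A)))
  expect_equal(same$overlapPct, 100)
  expect_equal(same$sizeDiffPct, 0)
  nested <- intermaskComparison(list(mk(A), mk(B)))
  expect_equal(nested$overlapPct, 50)
  expect_equal(nested$sizeDiffPct, 50)
  disj <- intermaskComparison(list(mk(B), mk(C)))
  expect_equal(disj$overlapPct, 0)
  expect_equal(disj$sizeDiffPct, 0)
  expect_error(intermaskComparison(list(mk(A))), "two masks")
})
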