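# Gaze binning, conditional masks, slope regression, population tests.

mkSes <- function(offsets) {
  nf <- length(offsets)
  new("SessionLog",
      frames = data.frame(frame_id = seq_len(nf),
                          onset_ms = (seq_len(nf) - 1) * 240,
                          duration_ms = 240, image_id = "a",
                          eye_x_deg = 0, eye_y_deg = offsets),
      spikes = numeric(0), maskCenters = list(), baseImages = list(),
      meta = list(type = "bubbles", size = 32, degPerPx = 1 / 16,
                  sigma = 7, nWindows = 20))
}

mkBinned <- function(centroidsY, means, degPerPxVal = 1 / 16) {
  stms <- lapply(centroidsY, function(cy) {
    lab <- matrix(0L, 32, 32); lab[16, 16] <- 1L
    w <- matrix(0, 32, 32); w[16, 16] <- 1
    new("SpikeTriggeredMask", imageId = "a", weights = w, labels = lab,
        area = 1, centroid = c(x = 16, y = cy), valid = TRUE,
        meta = list())
  })
  new("GazeBinnedSTM", binEdges = seq(-1, 1, length.out = 5),
      binMeans = means, stms = stms, counts = rep(100, length(means)),
      valid = rep(TRUE, length(means)))
}

test_that("gaze binning is an equal-count quantile partition", {
  off <- withr::with_seed(1, runif(2001, -1, 1))
  p <- binByGaze(mkSes(off), nBins = 4, minFrames = 100)
  expect_true(max(p$counts) - min(p$counts) <= 1)
  expect_equal(sum(p$counts), 2001)
  expect_lt(max(abs(p$edges[2:4] - c(-0.5, 0, 0.5))), 0.06)
  expect_true(all(diff(p$means) > 0))
  # membership respects the ordering: every bin-1 offset < bin-4 offsets
  expect_lt(max(off[p$bins[[1]]]), min(off[p$bins[[4]]]))
  # degenerate: identical offsets
  pd <- binByGaze(mkSes(rep(0.1, 500)), nBins = 4, minFrames = 100)
  expect_true(pd$degenerate)
  expect_false(any(pd$valid))
  expect_error(binByGaze(mkSes(off[1:200]), nBins = 4, minFrames = 100),
               "insufficient-data")
})

test_that("invariance slope reflects centroid tracking of gaze", {
  dpp <- 1 / 16
  means <- c(-0.6, -0.2, 0.2, 0.6)
  # centroids exactly tracking gaze (in px: 16 + mean/dpp) -> slope 1
  track <- mkBinned(16 + means / dpp, means, dpp)
  sl <- invarianceSlope(track, dpp)
  expect_equal(sl$slope, 1, tolerance = 1e-9)
  expect_true(sl$valid)
  # constant centroids -> slope 0
  flat <- invarianceSlope(mkBinned(rep(16, 4), means, dpp), dpp)
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  # fewer than 3 valid bins -> invalid
  few <- mkBinned(16 + means / dpp, means, dpp)
  few@valid <- c(TRUE, TRUE, FALSE, FALSE)
  expect_false(invarianceSlope(few, dpp)$valid)
})

test_that("conditional masks of a retinotopic neuron shift with gaze", {
  img <- generateBaseImage(64, 1, 1 / 24, id = "a", seed = 31)
  n <- templateNeuronFor(img, c(32, 32), mode = "energy",
                         positionCoding = 0, gain = 100, threshold = 0)
  eye <- makeEyeTrace(1600, 0.3, seed = 32)
  ses <- simulateBubbleSession(n, img, 1600, eyeTrace = eye, seed = 33)
  part <- binByGaze(ses, 4, 100)
  gb <- conditionalSTMs(ses, part, "a", nShuffles = 300,
                        minFrames = 100, seed = 34)
  sl <- invarianceSlope(gb, 1 / 24)
  expect_true(sl$valid)
  expect_equal(sl$slope, 1, tolerance = 0.35)
  # head-centered neuron on the same stimulus history: slope near 0 and
  # per-bin centroids within a bubble width of each other
  nH <- templateNeuronFor(img, c(32, 32), mode = "energy",
                          positionCoding = 1, gain = 100, threshold = 0)
  sesH <- simulateBubbleSession(nH, img, 1600, eyeTrace = eye, seed = 33)
  gbH <- conditionalSTMs(sesH, binByGaze(sesH, 4, 100), "a",
                         nShuffles = 300, minFrames = 100, seed = 34)
  slH <- invarianceSlope(gbH, 1 / 24)
  expect_true(slH$valid)
  expect_equal(slH$slope, 0, tolerance = 0.2)
  cys <- vapply(gbH@stms[gbH@valid], function(s) stmCentroid(s)[["y"]],
                numeric(1))
  expect_lt(diff(range(cys)), 2 * 7)
  # shifting all offsets by a constant leaves the head-centered slope ~0
  eyeShift <- eye
  eyeShift@frames$y_deg <- pmin(1, eye@frames$y_deg + 0.2)
  sesS <- simulateBubbleSession(nH, img, 1600, eyeTrace = eyeShift,
                                seed = 33)
  slS <- invarianceSlope(
    conditionalSTMs(sesS, binByGaze(sesS, 4, 100), "a", nShuffles = 300,
                    minFrames = 100, seed = 34), 1 / 24)
  expect_equal(slS$slope, 0, tolerance = 0.2)
})

test_that("population tests behave at the distribution extremes", {
  all1 <- data.frame(neuron = rep(letters[1:5], each = 2),
                     slope = 1 + rep(c(-0.01, 0.01), 5))
  r1 <- populationSlopeTests(all1)
  expect_gt(r1$tVs1$p, 0.4)      # cannot reject slope = 1
  expect_lt(r1$tVs0$p, 1e-6)     # clearly above 0
  # analytic power case: N(0.3, 0.5^2), n = 100 rejects both extremes
  sl <- withr::with_seed(9, data.frame(neuron = as.character(1:100),
                                       slope = rnorm(100, 0.3, 0.5)))
  r <- populationSlopeTests(sl)
  expect_lt(r$tVs1$p, 0.01)
  expect_lt(r$tVs0$p, 0.01)
  # single slope: descriptive only
  r0 <- populationSlopeTests(data.frame(neuron = "a", slope = 0.5))
  expect_null(r0$tVs1)
  expect_equal(r0$mean, 0.5)
  # correlation with CRF radius is reported when supplied
  sl$crfRadiusDeg <- withr::with_seed(10, runif(100, 0.5, 2))
  rc <- populationSlopeTests(sl)
  expect_true(is.finite(rc$corRadius$estimate))
})
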