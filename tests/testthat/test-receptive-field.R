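# Spatial RF circle fit, SRF estimation, tuning curves and OSI.

makeProbeLog <- function(rates, gx, gy, degPerPxVal = 1 / 24,
                         repeats = 3) {
  # construct a probe session with deterministic per-cell spike counts
  cells <- expand.grid(x = gx, y = gy)
  idx <- rep(seq_len(nrow(cells)), repeats)
  onsets <- (seq_along(idx) - 1) * 200
  spk <- sort(unlist(lapply(seq_along(idx), function(i) {
    k <- round(rates[idx[i]] * 0.1)
    if (k > 0) onsets[i] + 100 + seq_len(k) * 0.01 else numeric(0)
  })))
  new("SessionLog",
      frames = data.frame(frame_id = seq_along(idx), onset_ms = onsets,
                          duration_ms = 200, probe_x_px = cells$x[idx],
                          probe_y_px = cells$y[idx], eye_x_deg = 0,
                          eye_y_deg = 0),
      spikes = spk, maskCenters = list(), baseImages = list(),
      meta = list(type = "probes", size = 64, degPerPx = degPerPxVal,
                  frameMs = 200))
}

test_that("spatial RF recovers a single hot cell and rejects flat maps", {
  gx <- seq(8, 56, by = 8)
  rates <- numeric(49)
  rates[25] <- 50  # center cell of the 7 x 7 grid (x = 32, y = 32)
  rf <- estimateSpatialRF(makeProbeLog(rates, gx, gx))
  expect_equal(rf@centerDeg, c(32, 32) / 24, tolerance = 0.05)
  # half-max contour of a single hot cell sits near half the grid pitch
  expect_equal(rf@radiusDeg, 4 / 24, tolerance = 0.35)
  expect_error(estimateSpatialRF(makeProbeLog(numeric(49), gx, gx)),
               "no-rf")
})

test_that("spatial RF radius recovers a disk-shaped sensitivity profile", {
  sfs <- c(1.5, 3, 6)
  n <- linearNeuronFor(64, 1 / 24, 67.5, 3, sfs, crfRadiusPx = 16)
  g <- round(seq(6, 58, length.out = 12))
  pr <- simulateProbeSession(n, g, g, probeSizePx = 4, repeats = 10,
                             seed = 5)
  rf <- estimateSpatialRF(pr)
  # ground truth: half-max radius of the soft CRF window (16 px radius,
  # 3 px cosine edge -> 14.5 px)
  expect_lt(abs(rf@radiusDeg * 24 - 14.5) / 14.5, 0.2)
  expect_equal(rf@centerDeg * 24, c(32.5, 32.5), tolerance = 0.1)
})

test_that("SRF estimation localizes constructed and simulated tuning", {
  # constructed log: spikes only after 45-degree frames
  oris <- c(0, 45, 90, 135)
  cells <- expand.grid(ori = oris, sf = c(1, 2), ph = c(0, 180))
  idx <- rep(seq_len(nrow(cells)), 8)
  onsets <- (seq_along(idx) - 1) * 100
  spk <- sort(unlist(lapply(seq_along(idx), function(i)
    if (cells$ori[idx[i]] == 45) onsets[i] + 100 + 0:3 else numeric(0))))
  ses <- new("SessionLog",
             frames = data.frame(frame_id = seq_along(idx),
                                 onset_ms = onsets, duration_ms = 100,
                                 ori_deg = cells$ori[idx],
                                 sf_cpd = cells$sf[idx],
                                 phase_deg = cells$ph[idx],
                                 eye_x_deg = 0, eye_y_deg = 0),
             spikes = spk, maskCenters = list(), baseImages = list(),
             meta = list(type = "gratings", size = 64, degPerPx = 1 / 24))
  srf <- estimateSRF(ses, minCount = 2)
  R <- srfMatrix(srf)
  expect_true(all(R[2, ] > 0))           # the 45-degree row
  expect_true(all(R[c(1, 3, 4), ] == 0))
  # frame-order invariance: permuting frames (with their spikes) leaves R
  # unchanged
  perm <- withr::with_seed(1, sample(length(idx)))
  f2 <- frames(ses)[perm, ]
  f2$onset_ms <- (seq_along(perm) - 1) * 100
  f2$frame_id <- seq_along(perm)
  sp2 <- sort(unlist(lapply(seq_along(perm), function(k)
    if (f2$ori_deg[k] == 45) f2$onset_ms[k] + 100 + 0:3 else numeric(0))))
  ses2 <- new("SessionLog", frames = f2, spikes = sp2,
              maskCenters = list(), baseImages = list(),
              meta = ses@meta)
  expect_equal(srfMatrix(estimateSRF(ses2, minCount = 2)), R)

  # parameter recovery on a simulated Gaussian-tuned neuron
  sfs <- c(1.5, 3, 6)
  n <- linearNeuronFor(64, 1 / 24, 67.5, 3, sfs)
  gr <- simulateGratingSession(n, ORIS8, sfs, nFrames = 5000, seed = 4)
  est <- estimateSRF(gr)
  pk <- arrayInd(which.max(srfMatrix(est)), dim(srfMatrix(est)))
  expect_equal(est@orientations[pk[1]], 67.5)
  expect_equal(est@spatialFreqs[pk[2]], 3)
})

test_that("undersampled SRF cells are flagged NA", {
  sfs <- c(1.5, 3)
  n <- linearNeuronFor(64, 1 / 24, 45, 1.5, sfs)
  gr <- simulateGratingSession(n, ORIS8, sfs, nFrames = 200, seed = 9)
  est <- estimateSRF(gr, minCount = 10)
  expect_true(any(is.na(est@tensor)))
  expect_true(all(est@counts[is.na(est@tensor)] < 10))
})

test_that("orientation tuning collapses the SRF correctly", {
  R <- matrix(3, 4, 5)
  ct <- orientationTuning(R, orientations = c(0, 45, 90, 135))
  expect_equal(ct$mean, rep(3, 4))
  expect_equal(ct$sd, rep(0, 4))
  # separable R = g(theta) h(f): curve proportional to g
  g <- c(1, 4, 2, 3); h <- c(1, 2, 3, 4, 5)
  cs <- orientationTuning(outer(g, h), orientations = c(0, 45, 90, 135))
  expect_equal(cs$mean / mean(h), g)
  # oracle: direct row averaging of a random matrix
  Rr <- withr::with_seed(2, matrix(runif(32), 8, 4))
  co <- orientationTuning(Rr, orientations = ORIS8)
  expect_equal(co$mean, rowMeans(Rr))
  expect_equal(co$sd, apply(Rr, 1, sd))
})

test_that("OSI is zero for flat curves and increases with concentration", {
  expect_equal(osi(rep(5, 8), ORIS8), 0)
  # direct arithmetic: pref 8, orth 1 -> 7
  r <- rep(1, 8); r[3] <- 8  # pref at 45, orth at 135 stays 1
  expect_equal(osi(r, ORIS8), 7)
  # von Mises curves of increasing concentration -> increasing OSI
  kappas <- c(0.5, 1, 2, 4, 8)
  osis <- vapply(kappas, function(k)
    osi(exp(k * cos(2 * (ORIS8 - 45) * pi / 180)), ORIS8), numeric(1))
  expect_true(all(diff(osis) > 0))
  expect_error(osi(c(1, 2, 3), c(0, 60, 120)), "4 orientation")
  expect_warning(o <- osi(c(0, 0, 1, 0, 0, 0, 0, 0), ORIS8), "capped")
  expect_equal(o, 100)
})
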