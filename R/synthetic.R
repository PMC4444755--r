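# Ground-truth model neurons, fixational eye traces, and complete
# simulated recording sessions (bubble, grating and probe streams).

#' Construct a ModelNeuron
#'
#' Builds the forward model and precomputes its linear-channel Fourier gain
#' and normalization (raw response to the optimal full-contrast grating, so
#' that the optimal grating yields a unit L response). See
#' [ModelNeuron-class] for the response equation.
#'
#' @param id neuron identifier.
#' @param size raster side length (pixels) of the stimuli this neuron will
#'   view.
#' @param degPerPx degrees per pixel.
#' @param srfGain orientation x spatial-frequency gain matrix (>= 0); all
#'   zeros (default) disables the spectral channel.
#' @param orientations,spatialFreqs grids for \code{srfGain}.
#' @param templates feature templates; see [ModelNeuron-class].
#' @param positionCoding v in \code{[0, 1]}: 0 retinotopic, 1
#'   head-centered.
#' @param threshold output threshold in drive units.
#' @param gain output gain, spikes/s per unit suprathreshold drive.
#' @param baseline spontaneous rate, spikes/s.
#' @param latencyMs response latency; default 100 ms.
#' @param crfCenterPx CRF window center (x, y); default raster center.
#' @param crfRadiusPx CRF window radius in pixels; default 3/8 of the
#'   raster.
#' @return a [ModelNeuron].
#' @export
modelNeuron <- function(id = "neuron", size, degPerPx,
                        srfGain = NULL, orientations = numeric(),
                        spatialFreqs = numeric(), templates = list(),
                        positionCoding = 0, threshold = 0, gain = 50,
                        baseline = 2, latencyMs = 100,
                        crfCenterPx = NULL, crfRadiusPx = NULL) {
  if (is.null(srfGain))
    srfGain <- matrix(0, max(length(orientations), 1),
                      max(length(spatialFreqs), 1))
  if (is.null(crfCenterPx)) crfCenterPx <- c(size, size) / 2 + 0.5
  if (is.null(crfRadiusPx)) crfRadiusPx <- size * 0.375
  lGain <- matrix(0, size, size)
  lNorm <- 1
  if (any(srfGain > 0)) {
    grid <- fftPolarGrid(size, degPerPx)
    lGain <- matrix(
      interpPolarGain(srfGain, orientations, spatialFreqs,
                      as.vector(grid$theta), as.vector(grid$f)),
      size, size)
    lGain[1, 1] <- 0
    pk <- arrayInd(which.max(srfGain), dim(srfGain))
    opt <- gratingRaster(orientations[pk[1]], spatialFreqs[pk[2]], 0, 1,
                         size, degPerPx)
    win <- crfWindow(size, crfCenterPx, crfRadiusPx)
    filt <- Re(stats::fft(stats::fft(opt - 0.5) * lGain,
                          inverse = TRUE)) / (size * size)
    lNorm <- sqrt(sum(win * filt^2))
    if (lNorm <= 0) lNorm <- 1
  }
  methods::new("ModelNeuron", id = id, srfGain = srfGain,
               orientations = orientations, spatialFreqs = spatialFreqs,
               templates = templates, positionCoding = positionCoding,
               threshold = threshold, gain = gain, baseline = baseline,
               latencyMs = latencyMs, crfCenterPx = crfCenterPx,
               crfRadiusPx = crfRadiusPx, size = size, degPerPx = degPerPx,
               lGain = lGain, lNorm = lNorm)
}

#' Gaussian orientation x spatial-frequency gain surface
#'
#' Convenience builder for quasi-linear model neurons: a separable
#' Gaussian bump over the grating parameter grid, wrapped in orientation
#' and log-spaced in spatial frequency.
#'
#' @param orientations orientation grid, degrees.
#' @param spatialFreqs spatial-frequency grid, cycles/degree.
#' @param prefOri preferred orientation, degrees.
#' @param prefSf preferred spatial frequency, cycles/degree.
#' @param oriSd orientation tuning width (degrees, circular SD); smaller =
#'   sharper tuning.
#' @param sfSdOct spatial-frequency tuning width in octaves.
#' @param floor additive pedestal in \code{[0, 1)} giving broadly tuned
#'   cells a non-zero response at all orientations.
#' @return gain matrix with unit peak.
#' @export
gaussianSRF <- function(orientations, spatialFreqs, prefOri, prefSf,
                        oriSd = 20, sfSdOct = 0.75, floor = 0) {
  dOri <- vapply(orientations, wrapDist, numeric(1), b = prefOri,
                 period = 180)
  gO <- exp(-dOri^2 / (2 * oriSd^2))
  gF <- exp(-(log2(spatialFreqs / prefSf))^2 / (2 * sfSdOct^2))
  g <- outer(gO, gF) * (1 - floor) + floor
  g / max(g)
}

#' Extract a feature template from a base image
#'
#' Cuts a square patch around \code{center} for use as an excitatory or
#' suppressive template of a [ModelNeuron].
#'
#' @param image a [BaseImage].
#' @param center patch center (x, y) in pixels.
#' @param sizePx patch side length in pixels (odd values center exactly).
#' @param weight template weight: > 0 excitatory, <= 0 suppressive.
#' @param mode \code{"match"} (default): drive is the projection onto the
#'   template pattern; \code{"energy"}: drive is the revealed RMS
#'   contrast inside the template footprint relative to the template's
#'   own contrast, a phase/pattern-tolerant selectivity.
#' @return list(center, raster, weight, mode), the template format of
#'   [ModelNeuron-class].
#' @export
templateFromImage <- function(image, center, sizePx = 15, weight = 1,
                              mode = c("match", "energy")) {
  mode <- match.arg(mode)
  px <- pixels(image)
  h <- floor((sizePx - 1) / 2)
  rows <- round(center[2]) - h + 0:(sizePx - 1)
  cols <- round(center[1]) - h + 0:(sizePx - 1)
  if (min(rows, cols) < 1 || max(rows) > nrow(px) || max(cols) > ncol(px))
    stop("template patch extends outside the image")
  list(center = as.numeric(center), raster = px[rows, cols],
       weight = weight, mode = mode)
}

# Soft circular CRF window: 1 inside radius - edge, cosine ramp to 0 at
# radius.
crfWindow <- function(size, centerPx, radiusPx, edgePx = 3) {
  x <- matrix(seq_len(size) - centerPx[1], size, size, byrow = TRUE)
  y <- matrix(seq_len(size) - centerPx[2], size, size)
  r <- sqrt(x^2 + y^2)
  w <- 0.5 * (1 + cos(pi * (r - (radiusPx - edgePx)) / edgePx))
  w[r <= radiusPx - edgePx] <- 1
  w[r >= radiusPx] <- 0
  w
}

# Resolve the template set for a given base image.
templateSetFor <- function(neuron, imageId) {
  tpl <- neuron@templates
  if (!length(tpl)) return(NULL)
  if (!is.null(imageId) && imageId %in% names(tpl)) return(tpl[[imageId]])
  if (any(c("excit", "suppr") %in% names(tpl))) return(tpl)
  tpl[[1]]
}

# Template drive at a (possibly shifted) center. Mode "match" (default):
# projection of the raster (relative to background) onto the
# mean-subtracted template pattern; 1 when the raster shows the template
# at full contrast, 0 for background or orthogonal content. Mode
# "energy": RMS contrast revealed inside the template footprint relative
# to the template's own contrast -- a phase/pattern-tolerant drive that
# responds to revealed local structure wherever the window lands.
templateProjection <- function(raster, template, centerPx, background) {
  t0 <- template$raster - mean(template$raster)
  ss <- sum(t0^2)
  if (ss == 0) return(0)
  m <- nrow(template$raster)
  h <- floor((m - 1) / 2)
  rows <- round(centerPx[2]) - h + 0:(m - 1)
  cols <- round(centerPx[1]) - h + 0:(m - 1)
  n <- nrow(raster)
  patch <- matrix(background, m, m)
  rOk <- rows >= 1 & rows <= n
  cOk <- cols >= 1 & cols <= n
  if (any(rOk) && any(cOk))
    patch[rOk, cOk] <- raster[rows[rOk], cols[cOk]]
  if (identical(template$mode, "energy"))
    sqrt(sum((patch - background)^2) / ss)
  else
    sum((patch - background) * t0) / ss
}

#' Firing rate of a model neuron for one stimulus frame
#'
#' Evaluates the forward model
#' \code{rate = baseline + gain * max(0, L + F - S - threshold)} on a
#' screen raster under a given eye offset. Template and CRF-window
#' positions are shifted by \code{(1 - positionCoding) * eyeOffset}
#' (in pixels), so a retinotopic neuron's driving region follows gaze
#' while a head-centered neuron's stays fixed in image coordinates.
#'
#' @param neuron a [ModelNeuron].
#' @param raster luminance matrix in screen/image coordinates.
#' @param eyeOffsetDeg eye offset (x, y) in degrees; default c(0, 0).
#' @param imageId base-image id used to select per-image templates.
#' @param background background gray level; default 0.5.
#' @return firing rate in spikes/s (>= 0).
#' @examples
#' n <- modelNeuron(size = 64, degPerPx = 1 / 16, gain = 30, baseline = 5)
#' driveRate(n, matrix(0.5, 64, 64))  # blank screen -> baseline
#' @export
driveRate <- function(neuron, raster, eyeOffsetDeg = c(0, 0),
                      imageId = NULL, background = 0.5) {
  shiftPx <- (1 - neuron@positionCoding) * eyeOffsetDeg / neuron@degPerPx
  L <- 0
  if (any(neuron@lGain > 0)) {
    n <- nrow(raster)
    win <- crfWindow(n, neuron@crfCenterPx + shiftPx, neuron@crfRadiusPx)
    # phase-invariant spectral channel: RMS of the SRF-filtered image
    # inside the CRF window (complex-cell-like energy model)
    filt <- Re(stats::fft(stats::fft(raster - background) * neuron@lGain,
                          inverse = TRUE)) / (n * n)
    L <- sqrt(sum(win * filt^2)) / neuron@lNorm
  }
  FF <- 0; S <- 0
  tpl <- templateSetFor(neuron, imageId)
  if (!is.null(tpl)) {
    if (!is.null(tpl$excit))
      FF <- tpl$excit$weight * max(0, templateProjection(
        raster, tpl$excit, tpl$excit$center + shiftPx, background))
    if (!is.null(tpl$suppr))
      S <- abs(tpl$suppr$weight) * max(0, templateProjection(
        raster, tpl$suppr, tpl$suppr$center + shiftPx, background))
  }
  max(0, neuron@baseline +
        neuron@gain * max(0, L + FF - S - neuron@threshold))
}

#' Generate a fixational eye-position trace
#'
#' Per-frame vertical offsets are drawn from a normal distribution
#' truncated to the 1-degree fixation window; horizontal offsets have one
#' third the vertical spread (fixational eye movements are predominantly
#' vertical in this preparation). Offsets are quantized to
#' \code{quantumDeg} so the per-frame mode of the sample series is well
#' defined and equals the frame offset.
#'
#' @param nFrames number of stimulus frames.
#' @param sdDeg vertical offset SD in degrees (<= 0.5); 0 gives perfect
#'   fixation.
#' @param frameMs frame duration, used to timestamp samples.
#' @param samplesPerFrame eye samples recorded per frame.
#' @param quantumDeg quantization step of the eye tracker, degrees.
#' @param seed optional integer seed.
#' @return an [EyeTrace].
#' @export
makeEyeTrace <- function(nFrames, sdDeg = 0.3, frameMs = 1000 / 4.25,
                         samplesPerFrame = 8, quantumDeg = 0.02,
                         seed = NULL) {
  if (sdDeg > 0.5) stop("sdDeg must be <= 0.5 within the fixation window")
  withSeed(seed, {
    draw <- function(n, sd) {
      if (sd == 0) return(numeric(n))
      u <- stats::runif(n, stats::pnorm(-1, 0, sd), stats::pnorm(1, 0, sd))
      stats::qnorm(u, 0, sd)
    }
    quant <- function(v) pmin(1, pmax(-1, round(v / quantumDeg) * quantumDeg))
    yv <- quant(draw(nFrames, sdDeg))
    xv <- quant(draw(nFrames, sdDeg / 3))
    framesDf <- data.frame(frame = seq_len(nFrames), x_deg = xv, y_deg = yv)
    nJit <- floor(samplesPerFrame / 3)
    sampleList <- lapply(seq_len(nFrames), function(i) {
      t0 <- (i - 1) * frameMs
      ts <- t0 + seq_len(samplesPerFrame) * frameMs / (samplesPerFrame + 1)
      jy <- c(rep(0, samplesPerFrame - nJit),
              sample(c(-1, 1), nJit, replace = TRUE) * quantumDeg)
      data.frame(t_ms = ts, x_deg = xv[i], y_deg = pmin(1, pmax(-1,
                 yv[i] + jy)))
    })
    methods::new("EyeTrace", frames = framesDf,
                 samples = do.call(rbind, sampleList))
  })
}

# Draw spikes for a vector of per-frame rates: counts are Poisson with
# mean rate * responseWindow, each spike placed at onset + lognormal
# latency (median latencyMs, ~10% spread).
drawSpikes <- function(rates, onsets, latencyMs, responseWindowMs) {
  counts <- stats::rpois(length(rates), rates * responseWindowMs / 1000)
  tot <- sum(counts)
  if (tot == 0) return(numeric(0))
  sort(rep(onsets, counts) + stats::rlnorm(tot, log(latencyMs), 0.1))
}

#' Simulate a bubble-masked natural-image session
#'
#' Renders a stream of bubble-masked frames (base image chosen at random
#' per frame, windows at uniform random positions), evaluates the model
#' neuron on every frame under the supplied eye trace, and draws Poisson
#' spikes at the neuron's latency. The returned log records everything
#' needed to re-render each frame bit-exactly (image ids and window
#' centers).
#'
#' @param neuron a [ModelNeuron].
#' @param baseImages a [BaseImage] or list of them.
#' @param nFrames number of stimulus frames.
#' @param eyeTrace optional [EyeTrace] (recycled per frame); NULL = fixed
#'   gaze.
#' @param nWindows,sigma bubble-mask parameters; defaults 20 windows of
#'   sigma 7 px.
#' @param frameMs frame duration; default 1000/4.25 ms (4.25 Hz).
#' @param background background gray level.
#' @param responseWindowMs length of the response integration window the
#'   expected spike count is scaled by; default 100 ms.
#' @param seed optional integer seed; same seed, same session.
#' @return a [SessionLog].
#' @export
simulateBubbleSession <- function(neuron, baseImages, nFrames,
                                  eyeTrace = NULL, nWindows = 20,
                                  sigma = 7, frameMs = 1000 / 4.25,
                                  background = 0.5,
                                  responseWindowMs = 100, seed = NULL) {
  if (methods::is(baseImages, "BaseImage")) baseImages <- list(baseImages)
  names(baseImages) <- vapply(baseImages, function(i) i@id, character(1))
  size <- nrow(pixels(baseImages[[1]]))
  if (!is.null(eyeTrace) && nrow(eyeTrace@frames) < nFrames)
    stop("eye trace shorter than the frame stream")
  withSeed(seed, {
    imgIdx <- sample(length(baseImages), nFrames, replace = TRUE)
    onsets <- (seq_len(nFrames) - 1) * frameMs
    ex <- if (is.null(eyeTrace)) numeric(nFrames) else
      eyeTrace@frames$x_deg[seq_len(nFrames)]
    ey <- if (is.null(eyeTrace)) numeric(nFrames) else
      eyeTrace@frames$y_deg[seq_len(nFrames)]
    maskCenters <- vector("list", nFrames)
    rates <- numeric(nFrames)
    for (i in seq_len(nFrames)) {
      ctr <- matrix(stats::runif(2 * nWindows, 0.5, size + 0.5), ncol = 2)
      maskCenters[[i]] <- ctr
      tr <- bubbleTransparency(size, ctr, sigma)
      img <- baseImages[[imgIdx[i]]]
      masked <- tr * pixels(img) + (1 - tr) * background
      rates[i] <- driveRate(neuron, masked, c(ex[i], ey[i]), img@id,
                            background)
    }
    spk <- drawSpikes(rates, onsets, neuron@latencyMs, responseWindowMs)
    framesDf <- data.frame(
      frame_id = seq_len(nFrames), onset_ms = onsets,
      duration_ms = frameMs, image_id = names(baseImages)[imgIdx],
      eye_x_deg = ex, eye_y_deg = ey)
    methods::new("SessionLog", frames = framesDf, spikes = spk,
                 maskCenters = maskCenters, baseImages = baseImages,
                 meta = list(type = "bubbles", size = size,
                             degPerPx = degPerPx(baseImages[[1]]),
                             frameMs = frameMs, sigma = sigma,
                             nWindows = nWindows, neuronId = neuron@id,
                             background = background,
                             latencyMs = neuron@latencyMs,
                             responseWindowMs = responseWindowMs))
  })
}

#' Simulate a dynamic grating session
#'
#' Presents gratings whose orientation, spatial frequency and phase are
#' drawn at random from the parameter grids on every frame (10 Hz by
#' default). Rates are memoized per unique grating, making long sessions
#' cheap.
#'
#' @param neuron a [ModelNeuron].
#' @param orientations,spatialFreqsCpd,phases grating parameter grids.
#' @param nFrames number of frames.
#' @param contrast grating contrast; default 1.
#' @param frameMs frame duration; default 100 ms (10 Hz).
#' @param innerDeg,outerDeg trapezoid envelope radii (degrees); defaults
#'   size the grating to the neuron's CRF.
#' @param background background gray level.
#' @param responseWindowMs response window scaling the expected count.
#' @param seed optional integer seed.
#' @return a [SessionLog] whose frames carry \code{ori_deg},
#'   \code{sf_cpd}, \code{phase_deg}.
#' @export
simulateGratingSession <- function(neuron, orientations, spatialFreqsCpd,
                                   phases = c(0, 90, 180, 270), nFrames,
                                   contrast = 1, frameMs = 100,
                                   innerDeg = NULL, outerDeg = NULL,
                                   background = 0.5,
                                   responseWindowMs = 100, seed = NULL) {
  size <- neuron@size
  if (is.null(innerDeg))
    innerDeg <- neuron@crfRadiusPx * neuron@degPerPx
  if (is.null(outerDeg)) outerDeg <- innerDeg * 1.25
  cells <- expand.grid(ori = orientations, sf = spatialFreqsCpd,
                       ph = phases)
  cellRate <- vapply(seq_len(nrow(cells)), function(k) {
    r <- gratingRaster(cells$ori[k], cells$sf[k], cells$ph[k], contrast,
                       size, neuron@degPerPx, innerDeg, outerDeg,
                       background)
    driveRate(neuron, r, c(0, 0), NULL, background)
  }, numeric(1))
  withSeed(seed, {
    idx <- sample(nrow(cells), nFrames, replace = TRUE)
    onsets <- (seq_len(nFrames) - 1) * frameMs
    spk <- drawSpikes(cellRate[idx], onsets, neuron@latencyMs,
                      responseWindowMs)
    framesDf <- data.frame(
      frame_id = seq_len(nFrames), onset_ms = onsets,
      duration_ms = frameMs, ori_deg = cells$ori[idx],
      sf_cpd = cells$sf[idx], phase_deg = cells$ph[idx],
      eye_x_deg = 0, eye_y_deg = 0)
    methods::new("SessionLog", frames = framesDf, spikes = spk,
                 maskCenters = list(), baseImages = list(),
                 meta = list(type = "gratings", size = size,
                             degPerPx = neuron@degPerPx,
                             frameMs = frameMs, neuronId = neuron@id,
                             background = background,
                             latencyMs = neuron@latencyMs,
                             responseWindowMs = responseWindowMs))
  })
}

#' Simulate a spatial-RF probe-mapping session
#'
#' Flashes a small bright probe in randomized order over an invisible
#' grid, as used to map the classical receptive field.
#'
#' @param neuron a [ModelNeuron].
#' @param gridXPx,gridYPx probe grid coordinates in pixels.
#' @param probeSizePx probe side length in pixels.
#' @param repeats presentations per grid cell.
#' @param frameMs frame duration; default 100 ms.
#' @param background background gray level.
#' @param responseWindowMs response window scaling the expected count.
#' @param seed optional integer seed.
#' @return a [SessionLog] whose frames carry \code{probe_x_px},
#'   \code{probe_y_px}.
#' @export
simulateProbeSession <- function(neuron, gridXPx, gridYPx,
                                 probeSizePx = 4, repeats = 10,
                                 frameMs = 100, background = 0.5,
                                 responseWindowMs = 100, seed = NULL) {
  size <- neuron@size
  cells <- expand.grid(x = gridXPx, y = gridYPx)
  cellRate <- vapply(seq_len(nrow(cells)), function(k) {
    r <- matrix(background, size, size)
    h <- floor(probeSizePx / 2)
    rows <- pmax(1, pmin(size, round(cells$y[k]) - h + 0:(probeSizePx - 1)))
    cols <- pmax(1, pmin(size, round(cells$x[k]) - h + 0:(probeSizePx - 1)))
    r[rows, cols] <- 1
    driveRate(neuron, r, c(0, 0), NULL, background)
  }, numeric(1))
  withSeed(seed, {
    idx <- sample(rep(seq_len(nrow(cells)), repeats))
    onsets <- (seq_along(idx) - 1) * frameMs
    spk <- drawSpikes(cellRate[idx], onsets, neuron@latencyMs,
                      responseWindowMs)
    framesDf <- data.frame(
      frame_id = seq_along(idx), onset_ms = onsets, duration_ms = frameMs,
      probe_x_px = cells$x[idx], probe_y_px = cells$y[idx],
      eye_x_deg = 0, eye_y_deg = 0)
    methods::new("SessionLog", frames = framesDf, spikes = spk,
                 maskCenters = list(), baseImages = list(),
                 meta = list(type = "probes", size = size,
                             degPerPx = neuron@degPerPx,
                             frameMs = frameMs, neuronId = neuron@id,
                             background = background,
                             latencyMs = neuron@latencyMs,
                             responseWindowMs = responseWindowMs))
  })
}
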