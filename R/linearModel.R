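# Quasi-linear prediction of driving features: amplitude-only Fourier
# filtering of the image by the (normalized) SRF, squared-pixel
# thresholding with area matching, and the 1 - SRF suppressive
# prediction; plus orientation-power and masked-image OSI analyses.

# Interpolate an (orientation x spatialFreq) matrix onto the FFT bins of a
# size x size raster; DC set to zero.
polarGainGrid <- function(R, oris, sfs, size, degPerPxVal) {
  grid <- fftPolarGrid(size, degPerPxVal)
  g <- matrix(interpPolarGain(R, oris, sfs, as.vector(grid$theta),
                              as.vector(grid$f)), size, size)
  g[1, 1] <- 0
  g
}

#' Build an amplitude-only Fourier filter from an SRF
#'
#' Maps every FFT bin of a \code{size x size} raster to polar
#' (spatial frequency, orientation) coordinates, interpolates the SRF
#' response matrix bilinearly (orientation wraps at 180 degrees; gain is
#' zero above the characterized frequency range), zeroes the DC bin, and
#' scales the gain so the peak squared response to the optimal
#' full-contrast grating equals one.
#'
#' @param srf an [SRF], or a plain gain matrix (then \code{orientations}
#'   and \code{spatialFreqsCpd} must be given).
#' @param size raster side length in pixels.
#' @param degPerPxVal degrees per pixel.
#' @param orientations,spatialFreqsCpd grids when \code{srf} is a matrix.
#' @return a [FourierFilter].
#' @export
buildSRFFilter <- function(srf, size, degPerPxVal, orientations = NULL,
                           spatialFreqsCpd = NULL) {
  if (methods::is(srf, "SRF")) {
    R <- srf@R; orientations <- srf@orientations
    spatialFreqsCpd <- srf@spatialFreqs
  } else R <- srf
  if (max(spatialFreqsCpd) * degPerPxVal > 0.5 + 1e-9)
    stop("SRF frequency grid exceeds the raster's resolvable range")
  R[is.na(R)] <- 0
  gain <- polarGainGrid(R, orientations, spatialFreqsCpd, size,
                        degPerPxVal)
  pk <- arrayInd(which.max(R), dim(R))
  opt <- gratingRaster(orientations[pk[1]], spatialFreqsCpd[pk[2]], 0, 1,
                       size, degPerPxVal)
  flt <- methods::new("FourierFilter", gain = gain, size = size,
                      degPerPx = degPerPxVal, scale = 1)
  peak <- max(filterImage(opt, flt))
  sc <- if (peak > 0) 1 / sqrt(peak) else 1
  methods::new("FourierFilter", gain = gain * sc, size = size,
               degPerPx = degPerPxVal, scale = sc)
}

#' Filter an image and square the result
#'
#' Forward FFT of the mean-subtracted image, amplitude multiplied by the
#' filter gain (phase preserved), inverse FFT real part, then elementwise
#' squaring: the squared filtered luminance used for driving-feature
#' prediction.
#'
#' @param image a [BaseImage] or numeric matrix.
#' @param filter a [FourierFilter].
#' @return numeric matrix of squared filtered pixel values.
#' @export
filterImage <- function(image, filter) {
  px <- if (methods::is(image, "BaseImage")) pixels(image) else image
  if (!all(dim(px) == filter@size))
    stop("image size does not match the filter")
  n <- nrow(px)
  F <- stats::fft(px - mean(px)) * filter@gain
  (Re(stats::fft(F, inverse = TRUE)) / (n * n))^2
}

#' Predict excitatory and suppressive driving features from an SRF
#'
#' Filters the image with the max-normalized SRF and finds the threshold
#' on the squared filtered pixels such that the number of above-threshold
#' pixels equals \code{targetArea} (the measured spike-triggered mask
#' size), breaking ties deterministically by descending value then
#' row-major index. The suppressive prediction filters with \code{1 -
#' SRF} (on the same normalized scale) and applies the same threshold.
#'
#' @param image a [BaseImage] or numeric matrix.
#' @param srf an [SRF], or a gain matrix plus \code{orientations} /
#'   \code{spatialFreqsCpd}.
#' @param targetArea matched excitatory pixel count (>= 1), from the
#'   measured mask.
#' @param degPerPxVal degrees per pixel.
#' @param orientations,spatialFreqsCpd grids when \code{srf} is a matrix.
#' @return a [PredictedMask].
#' @export
predictMasks <- function(image, srf, targetArea, degPerPxVal,
                         orientations = NULL, spatialFreqsCpd = NULL) {
  px <- if (methods::is(image, "BaseImage")) pixels(image) else image
  id <- if (methods::is(image, "BaseImage")) image@id else "image"
  if (targetArea < 1) stop("targetArea must be >= 1")
  if (targetArea > length(px)) stop("targetArea exceeds the raster size")
  if (methods::is(srf, "SRF")) {
    R <- srf@R; orientations <- srf@orientations
    spatialFreqsCpd <- srf@spatialFreqs
  } else R <- srf
  R[is.na(R)] <- 0
  Rn <- R / max(R)
  size <- nrow(px)
  fE <- buildSRFFilter(Rn, size, degPerPxVal, orientations,
                       spatialFreqsCpd)
  # suppressive gain on the same normalized scale and the same overall
  # scaling as the excitatory filter, so the shared threshold is
  # meaningful
  gS <- polarGainGrid(1 - Rn, orientations, spatialFreqsCpd, size,
                      degPerPxVal) * fE@scale
  fS <- methods::new("FourierFilter", gain = gS, size = size,
                     degPerPx = degPerPxVal, scale = fE@scale)
  FE <- filterImage(px, fE)
  FS <- filterImage(px, fS)
  v <- as.vector(FE)                       # column-major linear indices
  L <- seq_along(v)
  rowMajor <- ((L - 1) %% size) * size + ((L - 1) %/% size) + 1
  sel <- order(-v, rowMajor)[seq_len(targetArea)]
  excit <- matrix(FALSE, size, size)
  excit[sel] <- TRUE
  thr <- v[sel[targetArea]]
  methods::new("PredictedMask", imageId = id, excit = excit,
               suppr = FS > thr, threshold = thr)
}

#' Score a predicted mask against a measured spike-triggered mask
#'
#' Component-wise fractional overlap and size difference, each as a
#' percentage of the larger set of the pair. Pairs where both sets are
#' empty yield \code{NA} (excluded from averages).
#'
#' @param predicted a [PredictedMask].
#' @param measured a [SpikeTriggeredMask].
#' @return data.frame with one row per component (\code{excit},
#'   \code{suppr}) and columns \code{overlapPct}, \code{sizeDiffPct},
#'   \code{nPredicted}, \code{nMeasured}.
#' @export
scorePrediction <- function(predicted, measured) {
  lab <- stmLabels(measured)
  one <- function(P, M) {
    np <- sum(P); nm <- sum(M); mx <- max(np, nm)
    if (mx == 0) return(c(NA_real_, NA_real_, 0, 0))
    c(100 * sum(P & M) / mx, 100 * (mx - min(np, nm)) / mx, np, nm)
  }
  e <- one(predicted@excit, lab == 1)
  s <- one(predicted@suppr, lab == -1)
  data.frame(component = c("excit", "suppr"),
             overlapPct = c(e[1], s[1]), sizeDiffPct = c(e[2], s[2]),
             nPredicted = c(e[3], s[3]), nMeasured = c(e[4], s[4]))
}

#' Orientation power of the image content inside a pixel set
#'
#' Zeroes the image outside the set, subtracts the in-set mean, applies a
#' cosine taper at the set boundary (the binary set smoothed with a small
#' raised-cosine kernel) to suppress edge transients, FFTs, and sums
#' spectral power within orientation bins centered on the supplied grid.
#'
#' @param image a [BaseImage] or numeric matrix.
#' @param pixelSet logical matrix selecting the pixels (e.g. a mask
#'   component), non-empty.
#' @param orientations orientation bin centers in degrees (typically the
#'   SRF grid).
#' @param taperPx half-width of the boundary taper in pixels; default 3.
#' @return data.frame with columns \code{orientation} and \code{power}.
#' @export
orientationPower <- function(image, pixelSet, orientations,
                             taperPx = 3) {
  px <- if (methods::is(image, "BaseImage")) pixels(image) else image
  if (!any(pixelSet)) stop("pixel set is empty")
  n <- nrow(px)
  # raised-cosine kernel, FFT convolution of the binary set
  k <- 2 * taperPx + 1
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  ker <- matrix(0, n, n)
  idx <- c(n - taperPx + seq_len(taperPx), seq_len(taperPx + 1))
  ker[idx, idx] <- outer(hann, hann)
  ker <- ker / sum(ker)
  win <- Re(stats::fft(stats::fft(pixelSet + 0) * stats::fft(ker),
                       inverse = TRUE)) / (n * n)
  win <- pmin(1, pmax(0, win))
  centered <- (px - mean(px[pixelSet])) * win
  P <- Mod(stats::fft(centered))^2
  grid <- fftPolarGrid(n, 1)
  keep <- grid$f > 0
  th <- grid$theta[keep]
  # assign each bin to the nearest orientation center (wrapped)
  d <- vapply(orientations, function(o) wrapDist(th, o, 180),
              numeric(sum(keep)))
  bin <- max.col(-d, ties.method = "first")
  pow <- vapply(seq_along(orientations),
                function(i) sum(P[keep][bin == i]), numeric(1))
  data.frame(orientation = orientations, power = pow)
}

#' Orientation selectivity of the masked image content
#'
#' Applies the spike-triggered mask to the base image, computes the
#' absolute dot product between the masked (mean-subtracted) image and
#' each grating of a parameter grid, collapses over phase by the maximum
#' (phase-invariant pseudo-response) and over spatial frequency by the
#' mean, and summarizes the resulting orientation curve with [osi()].
#'
#' @param image the underlying [BaseImage] (or matrix).
#' @param stm a [SpikeTriggeredMask]; its excitatory component defines
#'   the mask (weights scaled to unit maximum).
#' @param orientations,spatialFreqsCpd,phases grating grids.
#' @param degPerPxVal degrees per pixel.
#' @return list with \code{curve} (data.frame orientation/mean/sd),
#'   \code{osi}, \code{prefOri}.
#' @export
imageMaskOSI <- function(image, stm, orientations, spatialFreqsCpd,
                         phases = c(0, 90, 180, 270), degPerPxVal) {
  px <- if (methods::is(image, "BaseImage")) pixels(image) else image
  lab <- stmLabels(stm)
  if (!any(lab == 1)) stop("mask has no excitatory component")
  w <- stmWeights(stm) * (lab == 1)
  w <- w / max(w)
  masked <- (px - mean(px)) * w
  n <- nrow(px)
  resp <- matrix(0, length(orientations), length(spatialFreqsCpd))
  for (i in seq_along(orientations)) {
    for (j in seq_along(spatialFreqsCpd)) {
      dots <- vapply(phases, function(ph) {
        g <- gratingRaster(orientations[i], spatialFreqsCpd[j], ph, 1, n,
                           degPerPxVal) - 0.5
        abs(sum(masked * g))
      }, numeric(1))
      resp[i, j] <- max(dots)
    }
  }
  curve <- orientationTuning(resp, orientations)
  list(curve = curve, osi = osi(curve),
       prefOri = orientations[which.max(curve$mean)])
}
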