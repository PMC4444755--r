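# Stimulus construction: 1/f base images, Gaussian bubble masks, masked
# frames, and trapezoid-windowed sinusoidal gratings.

#' Generate a synthetic base image with a 1/f^a amplitude spectrum
#'
#' Natural photographs have approximately 1/f amplitude spectra; this
#' generator produces grayscale surrogates by shaping the amplitude
#' spectrum of white Gaussian noise with \code{f^(-spectralExponent)}
#' (DC removed) and min-max rescaling the result to \code{[0, 1]}.
#' \code{spectralExponent = 0} yields white noise, \code{1} the classic
#' natural-image spectrum.
#'
#' @param size raster side length in pixels (>= 32).
#' @param spectralExponent spectral slope magnitude, typically in
#'   \code{[0.5, 2]}; 0 gives white noise.
#' @param degPerPx degrees of visual angle per pixel.
#' @param id image identifier.
#' @param seed optional integer seed; the same seed reproduces the raster
#'   bit-exactly.
#' @return a [BaseImage].
#' @examples
#' img <- generateBaseImage(64, spectralExponent = 1, seed = 1)
#' range(pixels(img))
#' @export
generateBaseImage <- function(size, spectralExponent = 1,
                              degPerPx = 1 / 32, id = "img", seed = NULL) {
  if (length(size) != 1 || size < 32) stop("size must be a scalar >= 32")
  if (spectralExponent < 0) stop("spectralExponent must be non-negative")
  px <- withSeed(seed, {
    noise <- matrix(stats::rnorm(size * size), size, size)
    fr <- fftFreqs(size)
    f <- sqrt(outer(fr^2, fr^2, "+"))
    amp <- ifelse(f > 0, f^(-spectralExponent), 0)
    shaped <- Re(stats::fft(stats::fft(noise) * amp, inverse = TRUE)) /
      (size * size)
    rng <- range(shaped)
    if (diff(rng) == 0) matrix(0.5, size, size) else
      (shaped - rng[1]) / diff(rng)
  })
  methods::new("BaseImage", id = id, pixels = px, degPerPx = degPerPx)
}

#' Radially averaged amplitude spectrum of an image
#'
#' Averages FFT amplitudes within integer radial-frequency rings (DC
#' excluded). Used to verify the spectral slope of generated base images.
#'
#' @param image a [BaseImage] or a numeric matrix.
#' @return data.frame with columns \code{f} (cycles/image) and
#'   \code{amplitude}.
#' @export
radialAmplitudeSpectrum <- function(image) {
  px <- if (methods::is(image, "BaseImage")) pixels(image) else image
  n <- nrow(px)
  A <- Mod(stats::fft(px - mean(px)))
  fr <- fftFreqs(n) * n
  rad <- round(sqrt(outer(fr^2, fr^2, "+")))
  keep <- rad > 0 & rad <= n / 2
  amp <- tapply(A[keep], rad[keep], mean)
  data.frame(f = as.numeric(names(amp)), amplitude = as.numeric(amp))
}

# Transparency field for a set of window centers: unit-peak Gaussians with
# wrapped (toroidal) distance, combined by the independent-occlusion rule
# T = 1 - prod(1 - g_i). Separable per window, so each window costs two
# 1-D Gaussian evaluations plus an outer product.
bubbleTransparency <- function(size, centerMat, sigma) {
  coords <- seq_len(size)
  opaque <- matrix(1, size, size)
  if (nrow(centerMat)) {
    for (k in seq_len(nrow(centerMat))) {
      gx <- exp(-wrapDist(coords, centerMat[k, 1], size)^2 / (2 * sigma^2))
      gy <- exp(-wrapDist(coords, centerMat[k, 2], size)^2 / (2 * sigma^2))
      opaque <- opaque * (1 - outer(gy, gx))
    }
  }
  1 - opaque
}

#' Draw a random bubble mask
#'
#' Places \code{nWindows} unit-peak Gaussian transparency windows at
#' centers drawn i.i.d. uniformly over the raster, combined by the
#' independent-occlusion rule \code{T = 1 - prod(1 - g_i)}. Gaussians are
#' evaluated with wrapped (toroidal) distance, under which the expected
#' visible fraction follows the closed form
#' \code{1 - (1 - 2*pi*sigma^2/size^2)^nWindows} (about 0.316 for the
#' default 20 windows of sigma 7 px on a 128 px raster).
#'
#' @param size raster side length in pixels.
#' @param nWindows number of Gaussian windows (>= 0); default 20.
#' @param sigma window width in pixels (> 0); default 7.
#' @param seed optional integer seed.
#' @return a [BubbleMask].
#' @examples
#' m <- makeBubbleMask(128, seed = 1)
#' visibleFraction(m)
#' @export
makeBubbleMask <- function(size, nWindows = 20, sigma = 7, seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (nWindows < 0) stop("nWindows must be non-negative")
  ctr <- withSeed(seed,
    matrix(stats::runif(2 * nWindows, min = 0.5, max = size + 0.5),
           ncol = 2))
  if (nWindows == 0) ctr <- matrix(numeric(0), 0, 2)
  colnames(ctr) <- c("x", "y")
  methods::new("BubbleMask", centers = ctr, sigma = sigma,
               transparency = bubbleTransparency(size, ctr, sigma))
}

#' Rebuild a BubbleMask from stored window centers
#'
#' Recomputes the transparency field deterministically (bit-exactly) from
#' centers and sigma, e.g. after reloading a serialized session.
#'
#' @param centers n x 2 matrix of (x, y) centers in pixels.
#' @param size raster side length.
#' @param sigma window width in pixels.
#' @return a [BubbleMask].
#' @export
bubbleMaskFromCenters <- function(centers, size, sigma = 7) {
  centers <- as.matrix(centers)
  colnames(centers) <- c("x", "y")
  methods::new("BubbleMask", centers = centers, sigma = sigma,
               transparency = bubbleTransparency(size, centers, sigma))
}

#' Blend a base image through a bubble mask
#'
#' Elementwise \code{out = T * image + (1 - T) * background}: fully
#' transparent pixels show the image, fully opaque pixels the uniform
#' background gray.
#'
#' @param image a [BaseImage] or numeric matrix.
#' @param mask a [BubbleMask] or numeric transparency matrix.
#' @param background background gray level; default 0.5.
#' @return numeric matrix, the masked frame.
#' @export
applyMask <- function(image, mask, background = 0.5) {
  px <- if (methods::is(image, "BaseImage")) pixels(image) else image
  tr <- if (methods::is(mask, "BubbleMask")) transparency(mask) else mask
  if (!identical(dim(px), dim(tr)))
    stop("image and mask dimensions do not match")
  tr * px + (1 - tr) * background
}

#' Visible fraction of a bubble mask
#'
#' Mean of the transparency field: the fraction of the underlying image
#' visible through the mask. About 0.32 for default masks.
#'
#' @param mask a [BubbleMask] or transparency matrix.
#' @return scalar in \code{[0, 1]}.
#' @export
visibleFraction <- function(mask) {
  tr <- if (methods::is(mask, "BubbleMask")) transparency(mask) else mask
  mean(tr)
}

#' Closed-form expected visible fraction of a bubble mask
#'
#' Expected mean transparency under the wrap/no-truncation convention:
#' \code{1 - (1 - 2*pi*sigma^2/size^2)^nWindows}.
#'
#' @param size raster side length in pixels.
#' @param nWindows number of Gaussian windows.
#' @param sigma window width in pixels.
#' @return scalar expected visible fraction.
#' @export
expectedVisibleFraction <- function(size, nWindows = 20, sigma = 7) {
  1 - (1 - 2 * pi * sigma^2 / size^2)^nWindows
}

# Raw sinusoid + trapezoid envelope shared by makeGrating and the forward
# model. Returns luminance in [0, 1] around the 0.5 background.
gratingRaster <- function(orientation, sfCpd, phaseDeg, contrast, size,
                          degPerPx, innerDeg = Inf, outerDeg = Inf,
                          background = 0.5) {
  fCpp <- sfCpd * degPerPx
  if (fCpp > 0.5) stop("spatial frequency exceeds the Nyquist limit")
  ctr <- (size + 1) / 2
  x <- matrix(seq_len(size) - ctr, size, size, byrow = TRUE)
  y <- matrix(seq_len(size) - ctr, size, size)
  th <- orientation * pi / 180
  s <- x * sin(th) + y * cos(th)
  g <- cos(2 * pi * fCpp * s + phaseDeg * pi / 180)
  if (is.finite(outerDeg)) {
    r <- sqrt(x^2 + y^2) * degPerPx
    alpha <- pmin(1, pmax(0, (outerDeg - r) /
                            max(outerDeg - innerDeg, 1e-12)))
    alpha[r <= innerDeg] <- 1
    g <- g * alpha
  }
  background * (1 + contrast * g)
}

#' Render a sinusoidal grating stimulus
#'
#' Renders a [GratingStim] as a luminance raster on the uniform gray
#' background, alpha-blended with the trapezoidal radial envelope (alpha 1
#' inside the inner radius, 0 outside the outer radius, linear between).
#' Orientation convention: angle of the iso-luminance bars, 0 degrees =
#' horizontal bars (modulation along the vertical axis).
#'
#' @param stim a [GratingStim], or orientation in degrees when the
#'   remaining parameters are given directly.
#' @param size raster side length in pixels.
#' @param degPerPx degrees per pixel; the spatial frequency must stay
#'   below the Nyquist limit \code{0.5 / degPerPx}.
#' @param background background gray level; default 0.5.
#' @return numeric luminance matrix in \code{[0, 1]}.
#' @examples
#' g <- gratingStim(45, 2, 0)
#' r <- makeGrating(g, 64, 1 / 16)
#' @export
makeGrating <- function(stim, size, degPerPx, background = 0.5) {
  stopifnot(methods::is(stim, "GratingStim"))
  gratingRaster(stim@orientation, stim@spatialFreq, stim@phase,
                stim@contrast, size, degPerPx, stim@innerDeg, stim@outerDeg,
                background)
}

#' Construct a GratingStim
#'
#' @param orientation bar orientation in degrees (reduced modulo 180 at
#'   rendering only via the sinusoid's symmetry; stored as given modulo
#'   360).
#' @param spatialFreq spatial frequency in cycles/degree.
#' @param phase spatial phase in degrees.
#' @param contrast contrast fraction; default 1.
#' @param innerDeg,outerDeg trapezoid envelope radii in degrees; default
#'   infinite (no envelope).
#' @return a [GratingStim].
#' @export
gratingStim <- function(orientation, spatialFreq, phase, contrast = 1,
                        innerDeg = Inf, outerDeg = Inf) {
  methods::new("GratingStim", orientation = orientation,
               spatialFreq = spatialFreq, phase = phase %% 360,
               contrast = contrast, innerDeg = innerDeg,
               outerDeg = outerDeg)
}
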