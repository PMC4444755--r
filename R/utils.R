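# Internal numerical helpers shared across modules.

# Run expr under a temporary seed when one is supplied; otherwise use the
# caller's RNG stream. All stochastic exports funnel through this.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# FFT bin frequencies in cycles/px for an N-point transform, in R's fft
# ordering (bin i holds frequency (i-1)/N, wrapped to (-1/2, 1/2]).
fftFreqs <- function(n) {
  half <- n %/% 2
  c(0:half, if (n - half - 1 > 0) -((n - half - 1):1)) / n
}

# Polar coordinates (spatial frequency in cycles/deg, orientation in
# degrees, [0, 180)) of every FFT bin of a size x size raster. Rows of the
# raster are y, columns are x; orientation 0 = horizontal bars = modulation
# along y, matching the grating convention.
fftPolarGrid <- function(size, degPerPx) {
  fr <- fftFreqs(size)
  fy <- matrix(fr, size, size)                 # varies along rows
  fx <- matrix(fr, size, size, byrow = TRUE)   # varies along columns
  list(f = sqrt(fx^2 + fy^2) / degPerPx,
       theta = (atan2(fx, fy) * 180 / pi) %% 180)
}

# Bilinear interpolation of an (orientation x spatialFreq) gain matrix at
# arbitrary (theta, f) points. Orientation wraps at 180 degrees; spatial
# frequency is clamped to the grid below its minimum and returns 0 above
# its maximum (out of the characterized passband).
interpPolarGain <- function(R, oris, sfs, theta, f) {
  R[is.na(R)] <- 0
  nO <- length(oris)
  period <- 180
  # orientation: wrap-aware bracketing on the sorted grid
  th <- theta %% period
  step <- if (nO > 1) c(diff(oris), period - oris[nO] + oris[1]) else period
  iLo <- findInterval(th, oris)
  iLo[iLo == 0] <- nO                       # below first grid point: wrap
  iHi <- ifelse(iLo == nO, 1L, iLo + 1L)
  oLo <- oris[iLo]
  span <- step[iLo]
  wO <- ((th - oLo) %% period) / span
  # spatial frequency: clamp below, zero above
  out <- f > max(sfs) + 1e-12
  fc <- pmin(pmax(f, sfs[1]), sfs[length(sfs)])
  jLo <- pmin(pmax(findInterval(fc, sfs), 1L), length(sfs) - 1L)
  if (length(sfs) == 1) jLo <- rep(1L, length(fc))
  jHi <- if (length(sfs) == 1) jLo else jLo + 1L
  wF <- if (length(sfs) == 1) rep(0, length(fc)) else
    (fc - sfs[jLo]) / (sfs[jHi] - sfs[jLo])
  g <- (1 - wO) * (1 - wF) * R[cbind(iLo, jLo)] +
       (1 - wO) * wF       * R[cbind(iLo, jHi)] +
       wO       * (1 - wF) * R[cbind(iHi, jLo)] +
       wO       * wF       * R[cbind(iHi, jHi)]
  g[out] <- 0
  g
}

# Wrapped (toroidal) 1-D distance on a period.
wrapDist <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Kasa algebraic least-squares circle fit: minimizes the algebraic distance
# sum((x^2 + y^2 - 2ax - 2by - c)^2) over (a, b, c); radius^2 = c + a^2 + b^2.
fitCircle <- function(x, y) {
  if (length(x) < 3) stop("circle fit needs at least 3 points")
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  beta <- qr.solve(A, b)
  r2 <- beta[3] + beta[1]^2 + beta[2]^2
  if (r2 <= 0) stop("degenerate circle fit")
  list(center = c(beta[1], beta[2]), radius = sqrt(r2))
}

# Bilinear upsampling of a matrix by an integer factor, sampling the
# original nodes at their grid positions.
upsampleBilinear <- function(m, factor = 4) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 2) return(m)
  ri <- seq(1, nr, length.out = (nr - 1) * factor + 1)
  ci <- seq(1, nc, length.out = (nc - 1) * factor + 1)
  r0 <- pmin(floor(ri), nr - 1); wr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1); wc <- ci - c0
  out <- (1 - wr) %o% (1 - wc) * m[r0, c0] +
         (1 - wr) %o% wc       * m[r0, c0 + 1] +
         wr       %o% (1 - wc) * m[r0 + 1, c0] +
         wr       %o% wc       * m[r0 + 1, c0 + 1]
  list(map = out, rows = ri, cols = ci)
}

# Spike counts in [onset + a, onset + b) per frame, half-open, via
# binary search on the sorted spike vector.
windowCounts <- function(onsets, spikeTimes, a, b) {
  if (!length(spikeTimes)) return(numeric(length(onsets)))
  lo <- findInterval(onsets + a, spikeTimes, left.open = TRUE)
  hi <- findInterval(onsets + b, spikeTimes, left.open = TRUE)
  hi - lo
}

# Per-row empirical quantiles of a matrix (rows = pixels, cols = shuffles).
rowQuantiles2 <- function(m, pLo, pHi) {
  q <- apply(m, 1, stats::quantile, probs = c(pLo, pHi), names = FALSE,
             type = 7)
  list(lo = q[1, ], hi = q[2, ])
}

# Coerce the various mask representations (3-D array, list of matrices or
# BubbleMask objects, or an already-flat matrix) to a pixels x frames matrix.
asMaskMatrix <- function(masks) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    d <- dim(masks)
    return(list(M = matrix(masks, d[1] * d[2], d[3]), dim = d[1:2]))
  }
  if (is.list(masks)) {
    first <- masks[[1]]
    if (methods::is(first, "BubbleMask"))
      masks <- lapply(masks, transparency)
    d <- dim(masks[[1]])
    return(list(M = vapply(masks, as.vector, numeric(prod(d))), dim = d))
  }
  stop("masks must be a 3-D array or a list of matrices/BubbleMask objects")
}

# |weight|-weighted centroid (x, y) of the pixels where sel is TRUE.
weightedCentroid <- function(weights, sel) {
  if (!any(sel)) return(c(NA_real_, NA_real_))
  idx <- which(sel, arr.ind = TRUE)
  w <- abs(weights[sel])
  c(x = sum(idx[, 2] * w) / sum(w), y = sum(idx[, 1] * w) / sum(w))
}
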