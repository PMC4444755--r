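# Classical spatial RF (circle fit to the half-max contour) and the
# phase-collapsed spectral receptive field from grating sessions.

# Mean rate (spikes/s) per frame in [onset + latency, onset + latency +
# window), shared by the RF estimators and the STM pipeline.
responseRates <- function(session, latencyMs, windowMs) {
  f <- frames(session)
  windowCounts(f$onset_ms, spikes(session), latencyMs,
               latencyMs + windowMs) / (windowMs / 1000)
}

#' Estimate the classical spatial receptive field from a probe session
#'
#' Averages the response rate per probe grid cell, upsamples the map
#' bilinearly, extracts the half-maximal iso-response contour and fits a
#' circle to it by algebraic least squares. Returns center and radius in
#' degrees.
#'
#' @param session a probe [SessionLog] (frames with \code{probe_x_px},
#'   \code{probe_y_px}).
#' @param latencyMs,windowMs response window; defaults 50 and 100 ms.
#' @param upsample integer upsampling factor for the contour extraction.
#' @return a [SpatialRF].
#' @export
estimateSpatialRF <- function(session, latencyMs = 50, windowMs = 100,
                              upsample = 4) {
  f <- frames(session)
  if (!all(c("probe_x_px", "probe_y_px") %in% names(f)))
    stop("session does not look like a probe session")
  rates <- responseRates(session, latencyMs, windowMs)
  gx <- sort(unique(f$probe_x_px))
  gy <- sort(unique(f$probe_y_px))
  map <- matrix(0, length(gy), length(gx),
                dimnames = list(gy, gx))
  agg <- tapply(rates, list(factor(f$probe_y_px, levels = gy),
                            factor(f$probe_x_px, levels = gx)), mean)
  map[] <- ifelse(is.na(agg), 0, agg)
  if (max(map) - min(map) <= 0)
    stop("no-rf: response map is uniform", call. = FALSE)
  up <- upsampleBilinear(map, upsample)
  level <- min(map) + 0.5 * (max(map) - min(map))
  dpp <- degPerPx(session)
  xs <- stats::approx(seq_along(gx), gx, xout = up$cols)$y * dpp
  ys <- stats::approx(seq_along(gy), gy, xout = up$rows)$y * dpp
  # contourLines wants z[i, j] at x[i], y[j]; our map is [row=y, col=x]
  cl <- grDevices::contourLines(xs, ys, t(up$map), levels = level)
  if (!length(cl)) stop("no-rf: no half-max contour found", call. = FALSE)
  cx <- unlist(lapply(cl, `[[`, "x"))
  cy <- unlist(lapply(cl, `[[`, "y"))
  fit <- fitCircle(cx, cy)
  methods::new("SpatialRF", map = map, gridXDeg = gx * dpp,
               gridYDeg = gy * dpp, centerDeg = fit$center,
               radiusDeg = fit$radius)
}

#' Estimate the spectral receptive field from a grating session
#'
#' Parametric spike-triggered average in the grating parameter domain:
#' the response to each frame is the spike count in \code{[onset +
#' latency, onset + latency + window)} divided by the window length,
#' averaged within (orientation, spatial frequency, phase) cells and
#' collapsed across phase by averaging. Cells with fewer than
#' \code{minCount} frames are flagged \code{NA} and excluded downstream.
#'
#' @param session a grating [SessionLog].
#' @param latencyMs fixed response latency; default 50 ms.
#' @param windowMs integration window; default 100 ms.
#' @param minCount minimum frames per (ori, sf, phase) cell; default 5.
#' @return an [SRF].
#' @export
estimateSRF <- function(session, latencyMs = 50, windowMs = 100,
                        minCount = 5) {
  f <- frames(session)
  if (!all(c("ori_deg", "sf_cpd", "phase_deg") %in% names(f)))
    stop("session does not look like a grating session")
  rates <- responseRates(session, latencyMs, windowMs)
  oris <- sort(unique(f$ori_deg))
  sfs <- sort(unique(f$sf_cpd))
  phs <- sort(unique(f$phase_deg))
  fo <- factor(f$ori_deg, levels = oris)
  ff <- factor(f$sf_cpd, levels = sfs)
  fp <- factor(f$phase_deg, levels = phs)
  tens <- tapply(rates, list(fo, ff, fp), mean)
  cnt <- table(fo, ff, fp)
  tens[cnt < minCount] <- NA
  dim(tens) <- c(length(oris), length(sfs), length(phs))
  cntA <- array(as.numeric(cnt), dim(tens))
  R <- apply(tens, c(1, 2), mean, na.rm = TRUE)
  R[!is.finite(R)] <- NA
  methods::new("SRF", orientations = oris, spatialFreqs = sfs,
               phases = phs, R = R, tensor = tens, counts = cntA)
}

#' Orientation tuning curve from an SRF
#'
#' Per-orientation mean and SD of the phase-collapsed response across
#' spatial frequencies.
#'
#' @param srf an [SRF], or a plain orientation x spatial-frequency matrix
#'   (then \code{orientations} must be supplied).
#' @param orientations orientation grid when \code{srf} is a matrix.
#' @return data.frame with columns \code{orientation}, \code{mean},
#'   \code{sd}.
#' @export
orientationTuning <- function(srf, orientations = NULL) {
  if (methods::is(srf, "SRF")) {
    R <- srf@R; orientations <- srf@orientations
  } else R <- srf
  data.frame(orientation = orientations,
             mean = apply(R, 1, mean, na.rm = TRUE),
             sd = apply(R, 1, stats::sd, na.rm = TRUE))
}

#' Orientation selectivity index
#'
#' \code{OSI = (R_pref - R_orth) / R_orth}, where \code{R_pref} is the
#' maximum of the tuning curve and \code{R_orth} the response at the
#' orientation 90 degrees away (linearly interpolated with wrap-around
#' when off-grid). Zero for flat curves, unbounded above; when
#' \code{R_orth} is zero the index is capped at \code{cap} with a
#' warning.
#'
#' @param curve a data.frame as returned by [orientationTuning()], or a
#'   numeric vector of responses (then \code{orientations} must be
#'   given).
#' @param orientations orientation grid for a bare response vector.
#' @param cap value returned when the orthogonal response is zero.
#' @return non-negative scalar.
#' @export
osi <- function(curve, orientations = NULL, cap = 100) {
  if (is.data.frame(curve)) {
    r <- curve$mean; o <- curve$orientation
  } else {
    r <- curve; o <- orientations
  }
  keep <- is.finite(r)
  r <- r[keep]; o <- o[keep]
  if (length(r) < 4) stop("need at least 4 orientation samples")
  if (any(r < 0)) stop("curve must be non-negative")
  iPref <- which.max(r)
  oOrth <- (o[iPref] + 90) %% 180
  # interpolate with wrap-around on [0, 180)
  oExt <- c(o, o[1] + 180)
  rExt <- c(r, r[1])
  rOrth <- stats::approx(oExt, rExt, xout = oOrth, rule = 2)$y
  if (rOrth <= 0) {
    warning("orthogonal response is zero; OSI capped")
    return(cap)
  }
  (r[iPref] - rOrth) / rOrth
}
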