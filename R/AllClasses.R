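#' @import methods
NULL

#' BaseImage: a square grayscale luminance raster
#'
#' Container for a base image presented under bubble masking. Pixel values
#' are luminance in \code{[0, 1]} and the raster is square, with a spatial
#' calibration in degrees of visual angle per pixel. Matrices are indexed
#' \code{[row, col] = [y, x]}.
#'
#' @slot id character scalar identifying the image.
#' @slot pixels numeric matrix of luminance values in \code{[0, 1]}.
#' @slot degPerPx degrees of visual angle subtended by one pixel.
#'
#' @seealso [generateBaseImage()], [applyMask()]
#' @export
setClass("BaseImage",
  representation(id = "character", pixels = "matrix", degPerPx = "numeric"))

setValidity("BaseImage", function(object) {
  p <- object@pixels
  if (nrow(p) != ncol(p)) return("pixel raster must be square")
  if (nrow(p) < 32) return("raster must be at least 32 x 32")
  if (!all(is.finite(p))) return("pixel values must be finite")
  if (min(p) < 0 || max(p) > 1) return("pixel values must lie in [0, 1]")
  if (length(object@degPerPx) != 1 || object@degPerPx <= 0)
    return("degPerPx must be a positive scalar")
  TRUE
})

#' BubbleMask: transparency field built from Gaussian windows
#'
#' An opaque overlay perforated by \code{n} transparent, unit-peak Gaussian
#' windows at random centers. The per-pixel transparency field is a
#' deterministic function of the window centers and width:
#' \code{T = 1 - prod_i(1 - g_i)}, the independent-occlusion combination
#' rule, with each Gaussian evaluated under the wrapped (toroidal) distance
#' convention so mean coverage follows the closed form
#' \code{1 - (1 - 2*pi*sigma^2/N)^n}.
#'
#' @slot centers n x 2 matrix of window centers, columns \code{(x, y)} in
#'   pixel units.
#' @slot sigma Gaussian window width (standard deviation) in pixels.
#' @slot transparency numeric matrix in \code{[0, 1]}; 1 = fully visible.
#'
#' @seealso [makeBubbleMask()], [visibleFraction()], [applyMask()]
#' @export
setClass("BubbleMask",
  representation(centers = "matrix", sigma = "numeric",
                 transparency = "matrix"))

setValidity("BubbleMask", function(object) {
  if (ncol(object@centers) != 2 && nrow(object@centers) > 0)
    return("centers must be an n x 2 matrix")
  if (object@sigma <= 0) return("sigma must be positive")
  tr <- object@transparency
  if (min(tr) < -1e-12 || max(tr) > 1 + 1e-12)
    return("transparency must lie in [0, 1]")
  TRUE
})

#' GratingStim: parameters of a sinusoidal grating frame
#'
#' Orientation follows the bar-angle convention: 0 degrees means horizontal
#' iso-luminance bars (luminance modulated along the vertical axis), and
#' orientation is taken modulo 180. The trapezoidal envelope alpha-blends
#' the grating into the uniform gray background: alpha is 1 inside
#' \code{innerDeg}, 0 beyond \code{outerDeg}, and linear in between.
#'
#' @slot orientation bar orientation in degrees, \code{[0, 180)}.
#' @slot spatialFreq spatial frequency in cycles/degree.
#' @slot phase spatial phase in degrees, \code{[0, 360)}.
#' @slot contrast Michelson contrast fraction in \code{[0, 1]}.
#' @slot innerDeg inner (full-contrast) envelope radius in degrees.
#' @slot outerDeg outer (zero-contrast) envelope radius in degrees.
#'
#' @seealso [makeGrating()]
#' @export
setClass("GratingStim",
  representation(orientation = "numeric", spatialFreq = "numeric",
                 phase = "numeric", contrast = "numeric",
                 innerDeg = "numeric", outerDeg = "numeric"))

setValidity("GratingStim", function(object) {
  if (object@spatialFreq <= 0) return("spatialFreq must be positive")
  if (object@contrast < 0 || object@contrast > 1)
    return("contrast must lie in [0, 1]")
  if (object@outerDeg < object@innerDeg)
    return("outerDeg must be >= innerDeg")
  TRUE
})

#' EyeTrace: fixational eye-position record
#'
#' Per-frame modal offsets plus the raw sample series they summarize. All
#' offsets are confined to the 1-degree fixation window.
#'
#' @slot frames data.frame with columns \code{frame}, \code{x_deg},
#'   \code{y_deg}: the modal eye position for each stimulus frame.
#' @slot samples data.frame with columns \code{t_ms}, \code{x_deg},
#'   \code{y_deg}: the eye-position sample series.
#'
#' @seealso [makeEyeTrace()]
#' @export
setClass("EyeTrace",
  representation(frames = "data.frame", samples = "data.frame"))

setValidity("EyeTrace", function(object) {
  f <- object@frames
  if (!all(c("frame", "x_deg", "y_deg") %in% names(f)))
    return("frames must have columns frame, x_deg, y_deg")
  if (nrow(f) && max(abs(c(f$x_deg, f$y_deg))) > 1 + 1e-9)
    return("eye offsets exceed the 1 degree fixation window")
  TRUE
})

#' ModelNeuron: generative description of a synthetic visual neuron
#'
#' Forward model used to simulate recording sessions. The firing rate for a
#' screen raster \code{I} under eye offset \code{e} is
#' \deqn{r = baseline + gain \cdot \max(0, L + F - S - threshold)}
#' where \code{L} is the phase-invariant spectral channel (the RMS of the
#' image filtered by the neuron's orientation x spatial-frequency gain
#' surface, taken inside the CRF window and normalized so the optimal
#' full-contrast grating yields 1 -- a complex-cell-like energy model),
#' \code{F} is the drive of a localized excitatory feature template
#' (pattern projection or revealed contrast energy, see
#' [templateFromImage()]), and \code{S} the corresponding suppressive
#' drive (subtractive, entering before the output threshold). Template (and CRF-window) locations are shifted by
#' the eye offset scaled by \code{1 - positionCoding}: \code{positionCoding
#' = 0} gives a purely retinotopic neuron whose driving region moves with
#' gaze, \code{1} a head-centered neuron whose region is fixed in image
#' coordinates.
#'
#' @slot id character identifier.
#' @slot srfGain non-negative gain matrix over \code{(orientation,
#'   spatialFreq)}; all zeros disables the spectral channel.
#' @slot orientations orientation grid in degrees for \code{srfGain} rows.
#' @slot spatialFreqs spatial-frequency grid in cycles/degree for columns.
#' @slot templates list of feature-template sets. Either a single set
#'   (elements \code{excit} and/or \code{suppr}) applied to every base
#'   image, or a named list of such sets keyed by base-image id. Each
#'   template is a list with \code{center} (x, y in px), \code{raster}
#'   (template patch) and \code{weight} (> 0 excitatory, <= 0 suppressive).
#' @slot positionCoding scalar in \code{[0, 1]}; see above.
#' @slot threshold output threshold in drive units.
#' @slot gain output gain, spikes/s per unit suprathreshold drive.
#' @slot baseline spontaneous rate, spikes/s.
#' @slot latencyMs response latency in ms.
#' @slot crfCenterPx CRF window center (x, y) in pixels.
#' @slot crfRadiusPx CRF window radius in pixels.
#' @slot size raster size (pixels) the neuron was built for.
#' @slot degPerPx spatial calibration of that raster.
#' @slot lGain precomputed Fourier-domain gain grid of the L channel.
#' @slot lNorm normalization constant: raw L response to the optimal
#'   grating.
#'
#' @seealso [modelNeuron()], [driveRate()], [simulateBubbleSession()]
#' @export
setClass("ModelNeuron",
  representation(id = "character", srfGain = "matrix",
                 orientations = "numeric", spatialFreqs = "numeric",
                 templates = "list", positionCoding = "numeric",
                 threshold = "numeric", gain = "numeric",
                 baseline = "numeric", latencyMs = "numeric",
                 crfCenterPx = "numeric", crfRadiusPx = "numeric",
                 size = "numeric", degPerPx = "numeric",
                 lGain = "matrix", lNorm = "numeric"))

setValidity("ModelNeuron", function(object) {
  if (any(object@srfGain < 0)) return("srfGain must be non-negative")
  v <- object@positionCoding
  if (length(v) != 1 || v < 0 || v > 1)
    return("positionCoding must be a scalar in [0, 1]")
  if (object@gain <= 0) return("gain must be positive")
  if (object@baseline < 0) return("baseline must be non-negative")
  TRUE
})

#' SessionLog: one simulated (or ingested) recording session
#'
#' The single interchange object between stimulus generation / simulation
#' and all analysis stages. Frames are ordered, onsets strictly increasing;
#' bubble-mask frames carry their window centers so every stimulus can be
#' re-rendered bit-exactly from the log.
#'
#' @slot frames data.frame, one row per stimulus frame. Always has
#'   \code{frame_id}, \code{onset_ms}, \code{duration_ms}, \code{eye_x_deg},
#'   \code{eye_y_deg}; bubble sessions add \code{image_id}, grating
#'   sessions add \code{ori_deg}, \code{sf_cpd}, \code{phase_deg}, probe
#'   sessions add \code{probe_x_px}, \code{probe_y_px}.
#' @slot spikes sorted numeric vector of spike times in ms.
#' @slot maskCenters list (one n x 2 matrix per frame) of bubble-window
#'   centers; empty for non-bubble sessions.
#' @slot baseImages named list of [BaseImage] objects used in the session.
#' @slot meta list of session metadata: \code{type} ("bubbles", "gratings"
#'   or "probes"), \code{size}, \code{degPerPx}, \code{frameMs},
#'   \code{sigma}, \code{nWindows}, \code{neuronId}, \code{background}, ...
#'
#' @seealso [simulateBubbleSession()], [simulateGratingSession()],
#'   [writeSessionLog()]
#' @export
setClass("SessionLog",
  representation(frames = "data.frame", spikes = "numeric",
                 maskCenters = "list", baseImages = "list", meta = "list"))

setValidity("SessionLog", function(object) {
  f <- object@frames
  need <- c("frame_id", "onset_ms", "duration_ms")
  if (!all(need %in% names(f)))
    return("frames must have frame_id, onset_ms, duration_ms")
  if (nrow(f) > 1 && any(diff(f$onset_ms) <= 0))
    return("frame onsets must be strictly increasing")
  s <- object@spikes
  if (length(s) && (is.unsorted(s) || min(s) < 0))
    return("spike times must be sorted and non-negative")
  TRUE
})

#' SpatialRF: classical receptive field summary
#'
#' Per-cell response map over the probe grid plus the circle fitted to the
#' half-maximal iso-response contour of the (upsampled) map.
#'
#' @slot map mean response (spikes/s) per probe grid cell; rows index the
#'   vertical grid positions, columns the horizontal.
#' @slot gridXDeg,gridYDeg probe grid coordinates in degrees.
#' @slot centerDeg fitted circle center (x, y) in degrees.
#' @slot radiusDeg fitted circle radius in degrees.
#'
#' @seealso [estimateSpatialRF()], [maskMetrics()]
#' @export
setClass("SpatialRF",
  representation(map = "matrix", gridXDeg = "numeric", gridYDeg = "numeric",
                 centerDeg = "numeric", radiusDeg = "numeric"))

setValidity("SpatialRF", function(object) {
  if (object@radiusDeg <= 0) return("radiusDeg must be positive")
  if (length(object@centerDeg) != 2) return("centerDeg must be length 2")
  TRUE
})

#' SRF: phase-collapsed spectral receptive field
#'
#' Joint orientation x spatial-frequency response matrix estimated from a
#' dynamic grating sequence by parametric spike-triggered averaging, with
#' the pre-collapse per-phase tensor and per-cell frame counts retained.
#' Cells sampled fewer than \code{minCount} times are \code{NA}.
#'
#' @slot orientations orientation grid, degrees.
#' @slot spatialFreqs spatial-frequency grid, cycles/degree.
#' @slot phases phase grid, degrees.
#' @slot R phase-collapsed response matrix (orientation x spatialFreq),
#'   spikes/s.
#' @slot tensor per-phase response array (orientation x spatialFreq x
#'   phase).
#' @slot counts frame counts per (orientation, spatialFreq, phase) cell.
#'
#' @seealso [estimateSRF()], [orientationTuning()], [buildSRFFilter()]
#' @export
setClass("SRF",
  representation(orientations = "numeric", spatialFreqs = "numeric",
                 phases = "numeric", R = "matrix", tensor = "array",
                 counts = "array"))

setValidity("SRF", function(object) {
  if (nrow(object@R) != length(object@orientations) ||
      ncol(object@R) != length(object@spatialFreqs))
    return("R dimensions must match the orientation/spatialFreq grids")
  if (any(object@R < 0, na.rm = TRUE))
    return("R must be non-negative")
  TRUE
})

#' SpikeTriggeredMask: response-weighted mask average with significance
#'
#' The spike-triggered mask for one base image: the rate-weighted average
#' of bubble-mask transparency fields, minus the mean of the shuffle null,
#' with pixels inside the central \code{1 - alpha} null interval set to
#' zero. Surviving positive pixels are labeled excitatory (+1), negative
#' suppressive (-1).
#'
#' @slot imageId id of the base image the mask belongs to.
#' @slot weights null-mean-subtracted weight map (same size as the raster).
#' @slot labels integer matrix: +1 excitatory, -1 suppressive, 0 not
#'   significant.
#' @slot area number of significant pixels (excitatory + suppressive).
#' @slot centroid (x, y) centroid of the excitatory component, weighted by
#'   \code{|weights|}; \code{NA} when the excitatory component is empty.
#' @slot valid TRUE when at least one pixel is significant.
#' @slot meta list: \code{alpha}, \code{nShuffles}, \code{nFrames},
#'   \code{seed}, \code{nullMeanSubtracted}.
#'
#' @seealso [computeSTM()], [maskMetrics()], [similarityAnalysis()]
#' @export
setClass("SpikeTriggeredMask",
  representation(imageId = "character", weights = "matrix",
                 labels = "matrix", area = "numeric", centroid = "numeric",
                 valid = "logical", meta = "list"))

setValidity("SpikeTriggeredMask", function(object) {
  w <- object@weights; l <- object@labels
  if (!identical(dim(w), dim(l)))
    return("weights and labels must have identical dimensions")
  if (any(w[l == 1] <= 0)) return("excitatory pixels must have weight > 0")
  if (any(w[l == -1] >= 0)) return("suppressive pixels must have weight < 0")
  if (object@area != sum(l != 0))
    return("area must equal the number of significant pixels")
  TRUE
})

#' PredictedMask: driving features predicted by the quasi-linear model
#'
#' Excitatory pixels are the above-threshold squared pixel values of the
#' SRF-filtered image, with the threshold chosen so their count equals the
#' measured spike-triggered mask area; suppressive pixels are those of the
#' (1 - SRF)-filtered image exceeding the same threshold.
#'
#' @slot imageId base-image id.
#' @slot excit logical matrix of predicted excitatory pixels.
#' @slot suppr logical matrix of predicted suppressive pixels.
#' @slot threshold shared threshold in squared filtered-luminance units.
#'
#' @seealso [predictMasks()], [scorePrediction()]
#' @export
setClass("PredictedMask",
  representation(imageId = "character", excit = "matrix", suppr = "matrix",
                 threshold = "numeric"))

#' GazeBinnedSTM: conditional spike-triggered masks by eye position
#'
#' Spike-triggered masks recomputed separately for frames falling into each
#' modal-vertical-eye-position bin, for the translation-invariance
#' analysis.
#'
#' @slot binEdges bin boundaries in degrees (length nBins + 1).
#' @slot binMeans mean modal vertical eye position per bin, degrees.
#' @slot stms list of per-bin [SpikeTriggeredMask] objects (NULL for
#'   invalid bins).
#' @slot counts frames per bin.
#' @slot valid logical per bin: enough frames and a valid mask.
#'
#' @seealso [binByGaze()], [conditionalSTMs()], [invarianceSlope()]
#' @export
setClass("GazeBinnedSTM",
  representation(binEdges = "numeric", binMeans = "numeric", stms = "list",
                 counts = "numeric", valid = "logical"))

setValidity("GazeBinnedSTM", function(object) {
  if (is.unsorted(object@binEdges)) return("binEdges must be ordered")
  n <- length(object@counts)
  if (length(object@stms) != n || length(object@valid) != n ||
      length(object@binMeans) != n)
    return("per-bin slots must have equal length")
  TRUE
})

#' FourierFilter: amplitude-only Fourier-domain filter
#'
#' Per-FFT-bin amplitude gain derived from an SRF by polar interpolation,
#' DC excluded, scaled so the peak squared response to the optimal
#' full-contrast grating equals one.
#'
#' @slot gain amplitude gain per FFT bin (size x size matrix).
#' @slot size raster size the filter applies to.
#' @slot degPerPx spatial calibration.
#' @slot scale the normalization factor applied to the interpolated gain.
#'
#' @seealso [buildSRFFilter()], [filterImage()]
#' @export
setClass("FourierFilter",
  representation(gain = "matrix", size = "numeric", degPerPx = "numeric",
                 scale = "numeric"))
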