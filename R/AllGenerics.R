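# Accessor generics, methods and show() methods for the core classes.

#' Extract the pixel raster of a BaseImage
#' @param x a [BaseImage].
#' @return numeric matrix of luminance values.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "BaseImage", function(x) x@pixels)

#' Extract the transparency field of a BubbleMask
#' @param x a [BubbleMask].
#' @return numeric matrix in \code{[0, 1]}; 1 = fully visible.
#' @export
setGeneric("transparency", function(x) standardGeneric("transparency"))

#' @rdname transparency
#' @export
setMethod("transparency", "BubbleMask", function(x) x@transparency)

#' Extract bubble-window centers
#' @param x a [BubbleMask].
#' @return n x 2 matrix of (x, y) centers in pixels.
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname centers
#' @export
setMethod("centers", "BubbleMask", function(x) x@centers)

#' Spatial calibration in degrees per pixel
#' @param x an object carrying a spatial calibration.
#' @return numeric scalar.
#' @export
setGeneric("degPerPx", function(x) standardGeneric("degPerPx"))

#' @rdname degPerPx
#' @export
setMethod("degPerPx", "BaseImage", function(x) x@degPerPx)

#' @rdname degPerPx
#' @export
setMethod("degPerPx", "SessionLog", function(x) x@meta$degPerPx)

#' Frames table of a session log
#' @param x a [SessionLog].
#' @return data.frame of stimulus frames.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "SessionLog", function(x) x@frames)

#' Spike times of a session log
#' @param x a [SessionLog].
#' @return sorted numeric vector of spike times in ms.
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))

#' @rdname spikes
#' @export
setMethod("spikes", "SessionLog", function(x) x@spikes)

#' Phase-collapsed SRF response matrix
#' @param x an [SRF].
#' @return orientation x spatial-frequency matrix of responses (spikes/s).
#' @export
setGeneric("srfMatrix", function(x) standardGeneric("srfMatrix"))

#' @rdname srfMatrix
#' @export
setMethod("srfMatrix", "SRF", function(x) x@R)

#' Orientation grid
#' @param x an [SRF] or [ModelNeuron].
#' @return numeric vector of orientations in degrees.
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))

#' @rdname orientations
#' @export
setMethod("orientations", "SRF", function(x) x@orientations)

#' @rdname orientations
#' @export
setMethod("orientations", "ModelNeuron", function(x) x@orientations)

#' Spatial-frequency grid
#' @param x an [SRF] or [ModelNeuron].
#' @return numeric vector in cycles/degree.
#' @export
setGeneric("spatialFreqs", function(x) standardGeneric("spatialFreqs"))

#' @rdname spatialFreqs
#' @export
setMethod("spatialFreqs", "SRF", function(x) x@spatialFreqs)

#' @rdname spatialFreqs
#' @export
setMethod("spatialFreqs", "ModelNeuron", function(x) x@spatialFreqs)

#' Weight map of a spike-triggered mask
#' @param x a [SpikeTriggeredMask].
#' @return numeric matrix (null-mean-subtracted weights).
#' @export
setGeneric("stmWeights", function(x) standardGeneric("stmWeights"))

#' @rdname stmWeights
#' @export
setMethod("stmWeights", "SpikeTriggeredMask", function(x) x@weights)

#' Significance labels of a spike-triggered mask
#' @param x a [SpikeTriggeredMask].
#' @return integer matrix: +1 excitatory, -1 suppressive, 0 none.
#' @export
setGeneric("stmLabels", function(x) standardGeneric("stmLabels"))

#' @rdname stmLabels
#' @export
setMethod("stmLabels", "SpikeTriggeredMask", function(x) x@labels)

#' Centroid of the excitatory mask component
#' @param x a [SpikeTriggeredMask].
#' @return length-2 numeric (x, y) in pixels, or NA when empty.
#' @export
setGeneric("stmCentroid", function(x) standardGeneric("stmCentroid"))

#' @rdname stmCentroid
#' @export
setMethod("stmCentroid", "SpikeTriggeredMask", function(x) x@centroid)

setMethod("show", "BaseImage", function(object) {
  cat(sprintf("BaseImage '%s': %d x %d px, %.4f deg/px, range [%.3f, %.3f]\n",
              object@id, nrow(object@pixels), ncol(object@pixels),
              object@degPerPx, min(object@pixels), max(object@pixels)))
})

setMethod("show", "BubbleMask", function(object) {
  cat(sprintf(
    "BubbleMask: %d windows, sigma = %.1f px, %d x %d, visible fraction %.3f\n",
    nrow(object@centers), object@sigma, nrow(object@transparency),
    ncol(object@transparency), mean(object@transparency)))
})

setMethod("show", "SessionLog", function(object) {
  cat(sprintf("SessionLog (%s): %d frames, %d spikes, %s x %s px\n",
              object@meta$type %||% "?", nrow(object@frames),
              length(object@spikes), object@meta$size %||% "?",
              object@meta$size %||% "?"))
})

setMethod("show", "SRF", function(object) {
  pk <- arrayInd(which.max(object@R), dim(object@R))
  cat(sprintf(
    "SRF: %d orientations x %d spatial freqs x %d phases; peak at (%.0f deg, %.2f cpd)\n",
    length(object@orientations), length(object@spatialFreqs),
    length(object@phases), object@orientations[pk[1]],
    object@spatialFreqs[pk[2]]))
})

setMethod("show", "SpatialRF", function(object) {
  cat(sprintf("SpatialRF: center (%.3f, %.3f) deg, radius %.3f deg\n",
              object@centerDeg[1], object@centerDeg[2], object@radiusDeg))
})

setMethod("show", "SpikeTriggeredMask", function(object) {
  cat(sprintf(
    "SpikeTriggeredMask '%s': %s, %d significant px (%d excit, %d suppr)\n",
    object@imageId, if (object@valid) "valid" else "invalid",
    object@area, sum(object@labels == 1), sum(object@labels == -1)))
})

setMethod("show", "ModelNeuron", function(object) {
  cat(sprintf(
    "ModelNeuron '%s': v = %.2f, gain %.1f, baseline %.1f sp/s, %s L channel, %d template set(s)\n",
    object@id, object@positionCoding, object@gain, object@baseline,
    if (any(object@srfGain > 0)) "active" else "no",
    length(object@templates)))
})

setMethod("show", "GazeBinnedSTM", function(object) {
  cat(sprintf("GazeBinnedSTM: %d bins (%d valid), counts %s\n",
              length(object@counts), sum(object@valid),
              paste(object@counts, collapse = "/")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
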