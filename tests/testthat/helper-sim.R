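# Shared builders for simulated neurons and sessions. All fixtures are
# generated in code with fixed seeds.

ORIS8 <- seq(0, 157.5, by = 22.5)

# Quasi-linear neuron: Gaussian orientation x SF tuning, no templates.
linearNeuronFor <- function(size, degPerPxVal, prefOri, prefSf,
                            sfs, oriSd = 20, crfRadiusPx = size * 0.44,
                            gain = 100, baseline = 2, threshold = 0) {
  modelNeuron(id = "lin", size = size, degPerPx = degPerPxVal,
              srfGain = gaussianSRF(ORIS8, sfs, prefOri, prefSf,
                                    oriSd = oriSd),
              orientations = ORIS8, spatialFreqs = sfs,
              threshold = threshold, gain = gain, baseline = baseline,
              crfRadiusPx = crfRadiusPx)
}

# Feature-template neuron with excitatory and (optionally) suppressive
# patches cut from the base image.
templateNeuronFor <- function(img, excitCenter, supprCenter = NULL,
                              patchPx = 13, positionCoding = 0,
                              mode = "match", gain = 80, baseline = 2,
                              threshold = -0.2, supprWeight = -0.8) {
  tpl <- list(excit = templateFromImage(img, excitCenter, patchPx, 1,
                                        mode = mode))
  if (!is.null(supprCenter))
    tpl$suppr <- templateFromImage(img, supprCenter, patchPx,
                                   supprWeight, mode = mode)
  modelNeuron(id = "tpl", size = nrow(pixels(img)),
              degPerPx = degPerPx(img), templates = tpl,
              positionCoding = positionCoding, threshold = threshold,
              gain = gain, baseline = baseline)
}

# Scale the output gain so the unmasked base image evokes ~60 spikes/s.
calibrateGain <- function(neuron, img, target = 58) {
  d0 <- driveRate(neuron, pixels(img), c(0, 0), img@id) - neuron@baseline
  neuron@gain <- neuron@gain * target / max(d0, 0.05)
  neuron
}

# Logical matrix marking the footprint of a template patch.
patchFootprint <- function(size, center, patchPx = 13) {
  h <- floor((patchPx - 1) / 2)
  out <- matrix(FALSE, size, size)
  out[round(center[2]) - h + 0:(patchPx - 1),
      round(center[1]) - h + 0:(patchPx - 1)] <- TRUE
  out
}
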