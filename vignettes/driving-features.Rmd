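---
title: "Identifying neuronal driving features with bubble-masked natural images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying neuronal driving features with bubble-masked natural images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubbleSTM)
```

## The problem

Neurons in mid-level visual cortex (area V4 of the primate is the
motivating system) respond selectively to complex image features, but
their selectivity is poorly predicted by the classical linear picture
built from bars and gratings. This package implements an analysis chain
for a stimulus-masking experiment that localizes, pixel by pixel, the
image regions that actually modulate a neuron's firing — its *driving
features* — and then asks how well a linear spectral model predicts
them, and whether they are anchored to the retina or to the image when
the eye moves.

The experimental logic: a grayscale natural image is presented
repeatedly behind an opaque mask perforated by transparent Gaussian
windows ("bubbles") whose positions are redrawn uniformly at random on
every frame. Frames that happen to reveal a region the neuron cares
about evoke more (or, for suppressive regions, fewer) spikes. Averaging
the mask transparency fields weighted by the evoked response therefore
converges on a map of the pixels driving the response.

## Stimuli

Bubble masks combine `nWindows = 20` unit-peak Gaussian windows of
width `sigma = 7` px on a 128 px raster, placed i.i.d. uniformly, with
the independent-occlusion rule

$$T(x) \;=\; 1 - \prod_{i=1}^{n}\bigl(1 - g_i(x)\bigr),$$

where each $g_i$ is a unit-peak Gaussian. The combination rule keeps
$T \le 1$ naturally. Gaussians are evaluated with wrapped (toroidal)
distance, under which the expected visible fraction has the closed form
$1 - (1 - 2\pi\sigma^2/N)^{n} \approx 0.316$ for the defaults — matching
the protocol's ~32% mean coverage. (With hard truncation at the raster
edge the mean drops to about 29%, inconsistent with that figure; the
wrap convention is therefore part of the mask definition here.)

```{r}
mean(replicate(200, visibleFraction(makeBubbleMask(128, seed = NULL))))
expectedVisibleFraction(128, 20, 7)
```

Masked frames blend image and gray background as
`T * image + (1 - T) * background`. Base images are synthetic
$1/f^{a}$-spectrum rasters (`generateBaseImage()`); real photographs are
neither bundled nor required. Sinusoidal gratings follow the bar-angle
convention (0° = horizontal bars, luminance modulated along the
vertical axis) and are alpha-blended into the background with a
trapezoidal radial envelope.

## The synthetic neuron

No public recordings accompany the protocol, so a generative model
neuron (`modelNeuron()`) stands in for the data and defines ground
truth for every recovery test:

$$r \;=\; \text{baseline} + \text{gain}\cdot
  \max\bigl(0,\; L + F - S - \theta\bigr)$$

* **L, the spectral channel** — the RMS of the image filtered by the
  neuron's orientation × spatial-frequency gain surface, taken inside a
  soft circular CRF window and normalized so the optimal full-contrast
  grating gives $L = 1$. This is a phase-invariant (complex-cell-like)
  energy model. A pure amplitude-spectrum dot product was rejected
  during design: it is position-insensitive and globally integrating,
  so its spike-triggered masks carry almost no relation to the
  filtered-image energy map that the linear prediction thresholds,
  which would make the model-comparison analyses vacuous.
* **F and S, template channels** — localized excitatory and suppressive
  patches. Two drive modes exist: `"match"` (projection onto the
  mean-subtracted template pattern; 1 at a full-contrast exact match, 0
  for background or orthogonal content) and `"energy"` (revealed RMS
  contrast inside the template footprint, relative to the template's
  own). The energy mode exists for the translation-invariance
  simulations: with a *static* base image, pattern projection at
  gaze-shifted positions measures the image's self-similarity, which
  for 1/f noise is lumpy and occasionally sign-reversing, injecting
  heavy-tailed noise into centroid-versus-gaze slopes that has nothing
  to do with position coding. Energy drive emulates the
  pattern-tolerant selectivity the analysis is probing and leaves the
  position signal clean.
* **Position coding** — template and CRF-window centers shift with the
  eye offset scaled by $(1 - v)$. $v = 0$ is fully retinotopic (the
  driving region follows gaze through the image), $v = 1$ fully
  head-centered (the region is glued to the image); intermediate values
  span the continuum of partial invariance.
* **Suppression is subtractive** and enters before the output
  threshold. Extracellular masks constrain only the sign and location
  of suppression, not its algebra; subtractive was chosen and recorded
  here, and nothing downstream depends on the distinction at the
  simulated operating points.
* **Spiking is Poisson** per frame (no distributional claim is being
  tested), with spike times at a lognormal latency (median 100 ms,
  ~10 ms spread) so the fixed 50–150 ms analysis window captures
  essentially the whole response. Output gains in the shipped
  simulations are calibrated deterministically so the unmasked base
  image evokes ~60 spikes/s, a typical evoked rate for this area.

What the generator does *not* emulate: adaptation, spike-history
effects, saccadic dynamics, contrast normalization across frames, and
correlated trial-to-trial variability. Green recovery tests therefore
certify the *analysis chain* — estimator correctness, calibration of
the significance test, and identifiability at realistic counts — not
robustness of the method to every property of cortical data.

## Spike-triggered masks and the shuffle null

Per-frame responses $w_n$ are mean rates in a half-open window
50–150 ms after frame onset (`computeFrameResponses()`); windows of
consecutive frames may not overlap at the 4.25 Hz bubble rate. The raw
mask is $\sum_n w_n T_n / \sum_n w_n$. Significance
(`computeSTM()`) comes from a null ensemble built by shuffling the
responses across the frame ensemble and recomputing the average
(default 1000 shuffles): pixels inside the central $1-\alpha$ interval
of their null distribution are zeroed, and the null mean is subtracted
so surviving weights have a meaningful sign — positive pixels are
labeled excitatory, negative suppressive. The default $\alpha = 0.01$
(two-tailed, i.e. per-tail 99.5th percentiles) follows the protocol's
zeroing of pixels with $p > 0.01$; the per-tail quantile is the
configurable reading of its "99.5% confidence interval" phrasing, which
is internally inconsistent as printed.

Masks are never smoothed; because individual bubbles have spatial
extent, a mask is an *upper bound* on the driving pixels, blurred by
roughly the bubble width. Reported metrics: significant area, area as a
fraction of the CRF disk, the $|w|$-weighted excitatory centroid, a
flag for excitatory pixels escaping the CRF circle, pairwise overlap
and size difference between the masks of one neuron (percentages
relative to the larger mask), and the mask–frame similarity analysis
(dot product of the mask with every frame's transparency field,
and the mean response of frames above the 90th similarity percentile).

A deliberate choice: at least 50 frames per base image are required
before a mask is attempted, and conditional (gaze-binned) masks require
100 frames per bin; the protocol does not state its criteria, and these
floors keep the shuffle quantiles estimable.

## Receptive fields

The classical RF is summarized by a circle fitted (Kåsa algebraic least
squares) to the half-maximal iso-response contour of the probe-map,
upsampled ×4 with bilinear interpolation (bicubic would change the
contour by less than the probe spacing; bilinear keeps the package
dependency-free here). The spectral RF (`estimateSRF()`) is the
parametric spike-triggered average over the grating parameter grid —
response per frame at a fixed 50 ms latency with a 100 ms window,
averaged within (orientation, spatial frequency, phase) cells, cells
with fewer than 5 frames flagged `NA`, then collapsed across phase by
averaging. Orientation tuning is the mean ± SD across spatial
frequency, and

$$\mathrm{OSI} = \frac{R_{\text{pref}} - R_{\text{orth}}}{R_{\text{orth}}}$$

with $R_{\text{orth}}$ interpolated 90° from the preferred orientation.
This ratio form is adopted because the protocol's printed OSI range
(0.09–7.81) is unbounded above, which excludes the bounded
$(R_p - R_o)/(R_p + R_o)$ variant; a flat curve gives 0, and a zero
orthogonal response is capped at 100 with a warning.

## The quasi-linear prediction

`buildSRFFilter()` turns the (max-normalized) SRF into an
amplitude-only Fourier filter: every FFT bin maps to polar
$(f, \theta)$, the SRF is interpolated bilinearly with 180° orientation
wrap, DC is zeroed, frequencies above the characterized band get zero
gain (below it, the nearest grid value), and the whole gain is scaled so
the peak squared response to the optimal full-contrast grating is 1.
`filterImage()` preserves phase, multiplies amplitudes, and squares the
real part of the inverse transform. `predictMasks()` thresholds the
squared filtered image so the above-threshold count equals the measured
mask area (ties broken deterministically by value, then row-major
index), and predicts suppressive features by filtering with $1 -$
normalized SRF under the *same* threshold — both filters share one
scale, otherwise a shared threshold would be meaningless.
`scorePrediction()` reports component-wise overlap and size difference
as percentages of the larger set of each pair, with empty pairs
excluded as undefined rather than scored 0.

Orientation-power curves for the content inside a mask taper the binary
pixel set with a small raised-cosine kernel before the FFT (suppressing
boundary transients), and sum power into orientation bins centered on
the SRF grid. The masked-image OSI uses absolute dot products with a
grating set, collapsing phase by the maximum — mirroring the
phase-invariance of the neurons — and frequency by the mean. Because
the pseudo-response is an absolute value, its noise floor is positive,
so an isotropic region yields a small but non-zero OSI; tests compare
it against oriented content rather than against exactly zero.

## Translation invariance

Frames are partitioned into four equal-count bins of modal vertical eye
position (`binByGaze()`); equal-count was chosen over fixed-width edges
because the truncated-normal offset distribution starves fixed outer
bins. Conditional masks per bin share shuffle settings, and
`invarianceSlope()` regresses the vertical excitatory-centroid
coordinate (degrees) on the per-bin mean eye position: slope 1 =
retinotopic, 0 = invariant. With at most four points per regression,
individual slopes carry no significance; inference lives at the
population level (`populationSlopeTests()`): one-tailed t tests of the
per-mask and per-neuron-averaged slope distributions against 1 and
against 0, plus the correlation of per-neuron slope with CRF radius.
Vertical-only analysis matches the protocol (its subjects made
predominantly vertical fixational movements); the horizontal analysis
would be symmetric but is not exposed.

## Numerical and scale choices

Simulated problem sizes in the tests were chosen to sit where the
estimators have clearly entered their asymptotic regime while a full
suite run stays comfortably short: 64–96 px rasters, 2000–3000 bubble
frames per mask, 300–1000 shuffles, 4000–5000 grating frames, and 8
replicate sessions per position-coding level. The shuffle count floor
(`nShuffles >= max(200, 2/alpha)`) guarantees the tail quantiles exist;
empirical quantiles use R's default type 7. All randomness flows
through explicit seeds; rerunning any simulation or the pipeline with
the same seed reproduces spike trains, CSV tables and serialized
artifacts byte-for-byte.

Serialization is plain text (CSV/JSON/YAML) plus PNG for images and
overlays: bubble masks are stored as window centers at full floating
precision and transparency fields are recomputed exactly on load.

## Known limitations

* Mask resolution is bounded below by the bubble width; driving
  features smaller than ~σ are over-estimated in area, and the area
  metrics inherit that bias (upper bounds, as in the source protocol).
* The linear prediction scores depend on the measured mask area through
  the area-matching rule; very large masks inflate chance-level
  overlap, so between-group comparisons should match area regimes (the
  shipped group comparison does).
* `estimateSpatialRF()` assumes a single compact RF; multi-lobed maps
  will produce a circle through all half-max contours.
* The OSI is undefined (capped) for curves with a zero orthogonal
  response, which occurs for noise-free constructed inputs but not in
  practice.
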