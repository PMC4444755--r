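# Spike-triggered masks: response-weighted bubble-mask averages, shuffle
# null significance, mask metrics and the similarity-index analysis.

#' Per-frame evoked responses of a bubble session
#'
#' The response to frame n, \code{w_n}, is the mean firing rate in a
#' window 50-150 ms after stimulus onset (half-open: a spike exactly at
#' onset + 150 ms is excluded). Errors if the configured windows of
#' consecutive frames would overlap.
#'
#' @param session a [SessionLog].
#' @param window response window (start, end) in ms after onset; default
#'   c(50, 150).
#' @return data.frame with columns \code{frame_id} and \code{w} (spikes/s).
#' @export
computeFrameResponses <- function(session, window = c(50, 150)) {
  f <- frames(session)
  len <- diff(window)
  if (len <= 0) stop("window end must exceed window start")
  if (nrow(f) > 1 && any(diff(f$onset_ms) < len))
    stop("invalid-configuration: response windows of consecutive frames overlap")
  w <- windowCounts(f$onset_ms, spikes(session), window[1], window[2]) /
    (len / 1000)
  data.frame(frame_id = f$frame_id, w = w)
}

# Render the transparency fields of a bubble session as a pixels x frames
# matrix (optionally a subset of frames).
sessionMaskMatrix <- function(session, idx = NULL) {
  size <- session@meta$size
  sigma <- session@meta$sigma
  if (is.null(idx)) idx <- seq_along(session@maskCenters)
  M <- matrix(0, size * size, length(idx))
  for (k in seq_along(idx))
    M[, k] <- as.vector(
      bubbleTransparency(size, session@maskCenters[[idx[k]]], sigma))
  M
}

#' Raw (response-weighted) spike-triggered mask
#'
#' The rate-weighted average of the bubble-mask transparency fields,
#' \code{sum_n w_n T_n / sum_n w_n}, without null subtraction or
#' thresholding. Exposed mainly for inspection; [computeSTM()] performs
#' the full significance analysis.
#'
#' @param masks bubble masks: a pixels x frames matrix, a 3-D array, or a
#'   list of matrices / [BubbleMask] objects.
#' @param responses per-frame responses \code{w_n} (spikes/s).
#' @return weight-map matrix.
#' @export
rawSTM <- function(masks, responses) {
  mm <- if (is.matrix(masks)) list(M = masks, dim = NULL) else
    asMaskMatrix(masks)
  if (ncol(mm$M) != length(responses))
    stop("one response per mask is required")
  if (sum(responses) == 0)
    stop("empty-stm: all responses are zero", call. = FALSE)
  v <- as.vector(mm$M %*% responses) / sum(responses)
  if (is.null(mm$dim)) {
    n <- sqrt(nrow(mm$M))
    mm$dim <- c(n, n)
  }
  matrix(v, mm$dim[1], mm$dim[2])
}

#' Spike-triggered mask with shuffle-null pixel significance
#'
#' Computes the response-weighted mask average and tests every pixel
#' against a null distribution obtained by shuffling the responses across
#' the ensemble of mask stimuli and recomputing the average
#' \code{nShuffles} times. Pixels inside the central \code{1 - alpha}
#' interval of their null distribution are set to zero; surviving pixels
#' with positive (null-mean-subtracted) weight are labeled excitatory,
#' negative ones suppressive. A mask with no surviving pixel is flagged
#' invalid.
#'
#' @param masks bubble masks (matrix / array / list, as in [rawSTM()]).
#' @param responses per-frame responses \code{w_n}.
#' @param imageId base-image id stored on the result.
#' @param alpha two-tailed significance level; default 0.01 (central 99
#'   percent interval, per-tail 99.5th percentiles).
#' @param nShuffles number of response shuffles (>= 200, and at least
#'   \code{2 / alpha} so the tail quantiles are estimable); default 1000.
#' @param minFrames minimum number of frames required; default 50.
#' @param seed optional integer seed for the shuffle permutations.
#' @return a [SpikeTriggeredMask].
#' @examples
#' \donttest{
#' masks <- replicate(300, transparency(makeBubbleMask(32, 5, 3)),
#'                    simplify = FALSE)
#' w <- vapply(masks, function(m) 100 * m[16, 16], numeric(1))
#' stm <- computeSTM(masks, w, nShuffles = 200, seed = 1)
#' }
#' @export
computeSTM <- function(masks, responses, imageId = "image", alpha = 0.01,
                       nShuffles = 1000, minFrames = 50, seed = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (nShuffles < 200 || nShuffles < 2 / alpha)
    stop("invalid-configuration: too few shuffles for this alpha")
  mm <- if (is.matrix(masks)) list(M = masks, dim = NULL) else
    asMaskMatrix(masks)
  M <- mm$M
  n <- ncol(M)
  if (n < minFrames)
    stop(sprintf("insufficient-data: %d frames (< %d)", n, minFrames))
  if (length(responses) != n) stop("one response per mask is required")
  sw <- sum(responses)
  if (sw == 0) stop("empty-stm: all responses are zero", call. = FALSE)
  raw <- as.vector(M %*% responses) / sw
  W <- withSeed(seed, {
    vapply(seq_len(nShuffles), function(s) responses[sample.int(n)],
           numeric(n))
  })
  nullMaps <- (M %*% W) / sw
  nullMean <- rowMeans(nullMaps)
  q <- rowQuantiles2(nullMaps, alpha / 2, 1 - alpha / 2)
  weights <- raw - nullMean
  sig <- raw > q$hi | raw < q$lo
  lab <- integer(length(raw))
  lab[sig & weights > 0] <- 1L
  lab[sig & weights < 0] <- -1L
  dims <- mm$dim
  if (is.null(dims)) dims <- rep(sqrt(length(raw)), 2)
  wMat <- matrix(weights, dims[1], dims[2])
  lMat <- matrix(lab, dims[1], dims[2])
  methods::new("SpikeTriggeredMask", imageId = imageId, weights = wMat,
               labels = lMat, area = sum(lMat != 0),
               centroid = weightedCentroid(wMat, lMat == 1),
               valid = any(lMat != 0),
               meta = list(alpha = alpha, nShuffles = nShuffles,
                           nFrames = n, seed = seed,
                           nullMeanSubtracted = TRUE))
}

#' Spike-triggered masks for every base image of a session
#'
#' Groups frames by base image, computes per-frame responses, and runs
#' [computeSTM()] per image. Images with fewer than \code{minFrames}
#' frames are skipped with a message.
#'
#' @param session a bubble [SessionLog].
#' @param window response window in ms; default c(50, 150).
#' @param alpha,nShuffles,minFrames,seed passed to [computeSTM()].
#' @return named list of [SpikeTriggeredMask] objects.
#' @export
sessionSTMs <- function(session, window = c(50, 150), alpha = 0.01,
                        nShuffles = 1000, minFrames = 50, seed = NULL) {
  f <- frames(session)
  resp <- computeFrameResponses(session, window)
  out <- list()
  for (id in unique(f$image_id)) {
    idx <- which(f$image_id == id)
    if (length(idx) < minFrames) {
      message(sprintf("image '%s': %d frames < %d, skipped", id,
                      length(idx), minFrames))
      next
    }
    M <- sessionMaskMatrix(session, idx)
    out[[id]] <- computeSTM(M, resp$w[idx], imageId = id, alpha = alpha,
                            nShuffles = nShuffles, minFrames = minFrames,
                            seed = seed)
  }
  out
}

#' Size and position metrics of a spike-triggered mask
#'
#' Area of the significant set, its fraction of the classical RF disk
#' area, the excitatory centroid, and whether any excitatory pixel lies
#' outside the CRF circle.
#'
#' @param stm a [SpikeTriggeredMask].
#' @param spatialRF a [SpatialRF], or a CRF radius in degrees.
#' @param degPerPxVal degrees per pixel of the mask raster.
#' @param crfCenterPx CRF center in mask pixel coordinates; defaults to
#'   the raster center (stimuli are presented centered on the RF).
#' @return list with \code{areaPx}, \code{areaFractionOfCRF} (0-1),
#'   \code{centroid}, \code{crfOutsideFlag}.
#' @export
maskMetrics <- function(stm, spatialRF, degPerPxVal, crfCenterPx = NULL) {
  radiusDeg <- if (methods::is(spatialRF, "SpatialRF"))
    spatialRF@radiusDeg else spatialRF
  rPx <- radiusDeg / degPerPxVal
  lab <- stmLabels(stm)
  if (is.null(crfCenterPx))
    crfCenterPx <- c(ncol(lab), nrow(lab)) / 2 + 0.5
  areaPx <- sum(lab != 0)
  outside <- FALSE
  if (any(lab == 1)) {
    idx <- which(lab == 1, arr.ind = TRUE)
    d <- sqrt((idx[, 2] - crfCenterPx[1])^2 + (idx[, 1] - crfCenterPx[2])^2)
    outside <- any(d > rPx)
  }
  list(areaPx = areaPx,
       areaFractionOfCRF = areaPx / (pi * rPx^2),
       centroid = stmCentroid(stm),
       crfOutsideFlag = outside)
}

#' Similarity between the spike-triggered mask and the stimulus sequence
#'
#' Dot product between the spike-triggered mask weight map and each
#' frame's bubble-mask transparency field (negative values arise from the
#' suppressive components), plus the mean response of the frames at or
#' above the q-th similarity percentile for comparison with the unmasked
#' response.
#'
#' @param stm a [SpikeTriggeredMask].
#' @param masks frame masks (matrix / array / list as in [rawSTM()]).
#' @param responses per-frame responses (spikes/s).
#' @param unmaskedRate mean response to the unmasked image, if known.
#' @param q percentile threshold; default 90.
#' @return list with \code{similarity} (per frame), \code{threshold},
#'   \code{meanTopRate}, \code{unmaskedRate}.
#' @export
similarityAnalysis <- function(stm, masks, responses, unmaskedRate = NA,
                               q = 90) {
  mm <- if (is.matrix(masks)) list(M = masks, dim = NULL) else
    asMaskMatrix(masks)
  wv <- as.vector(stmWeights(stm) * (stmLabels(stm) != 0))
  if (length(wv) != nrow(mm$M))
    stop("stm and frame masks are on different rasters")
  sim <- as.vector(crossprod(mm$M, wv))
  thr <- stats::quantile(sim, q / 100, names = FALSE)
  list(similarity = sim, threshold = thr,
       meanTopRate = mean(responses[sim >= thr]),
       unmaskedRate = unmaskedRate)
}

#' Pairwise comparison of the spike-triggered masks of one neuron
#'
#' Fractional overlap of the significant pixel sets, as a percentage of
#' the larger mask of each pair, and the size difference as a percentage
#' of the larger mask.
#'
#' @param stms list of at least two [SpikeTriggeredMask] objects.
#' @return data.frame with columns \code{i}, \code{j}, \code{overlapPct},
#'   \code{sizeDiffPct}.
#' @export
intermaskComparison <- function(stms) {
  if (length(stms) < 2)
    stop("need at least two masks for a pairwise comparison")
  sets <- lapply(stms, function(s) stmLabels(s) != 0)
  pairs <- utils::combn(length(sets), 2)
  out <- data.frame(i = pairs[1, ], j = pairs[2, ], overlapPct = NA_real_,
                    sizeDiffPct = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- sets[[pairs[1, k]]]; b <- sets[[pairs[2, k]]]
    na <- sum(a); nb <- sum(b); mx <- max(na, nb)
    out$overlapPct[k] <- if (mx > 0) 100 * sum(a & b) / mx else NA_real_
    out$sizeDiffPct[k] <- if (mx > 0) 100 * (mx - min(na, nb)) / mx else
      NA_real_
  }
  out
}
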