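# Gaze-contingent spike-triggered mask analysis: equal-count binning of
# modal vertical eye position, conditional masks per bin, centroid-vs-gaze
# regression, and the population slope tests.

#' Partition session frames by modal vertical eye position
#'
#' Equal-count (quantile) partition: frames are ordered by modal vertical
#' offset and split into \code{nBins} contiguous groups whose counts
#' differ by at most one. A partition is degenerate (flagged, all bins
#' invalid) when every offset is identical.
#'
#' @param session a [SessionLog] with per-frame eye offsets.
#' @param nBins number of bins; default 4.
#' @param minFrames minimum frames per bin for a bin to be usable;
#'   default 100.
#' @return list with \code{bins} (frame-index vectors), \code{edges}
#'   (degrees), \code{means} (mean offset per bin), \code{counts},
#'   \code{valid}, \code{degenerate}.
#' @export
binByGaze <- function(session, nBins = 4, minFrames = 100) {
  off <- frames(session)$eye_y_deg
  n <- length(off)
  if (n < nBins * minFrames)
    stop(sprintf("insufficient-data: %d frames < %d bins x %d", n, nBins,
                 minFrames))
  degenerate <- diff(range(off)) == 0
  ord <- order(off)
  sizes <- rep(n %/% nBins, nBins)
  extra <- n %% nBins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  stopEnd <- cumsum(sizes)
  startAt <- c(1, utils::head(stopEnd, -1) + 1)
  bins <- lapply(seq_len(nBins),
                 function(b) sort(ord[startAt[b]:stopEnd[b]]))
  sortedOff <- off[ord]
  edges <- c(sortedOff[1],
             (sortedOff[utils::head(stopEnd, -1)] +
              sortedOff[utils::head(stopEnd, -1) + 1]) / 2,
             sortedOff[n])
  list(bins = bins, edges = edges,
       means = vapply(bins, function(i) mean(off[i]), numeric(1)),
       counts = lengths(bins),
       valid = if (degenerate) rep(FALSE, nBins) else
         lengths(bins) >= minFrames,
       degenerate = degenerate)
}

#' Conditional spike-triggered masks per gaze bin
#'
#' Recomputes the spike-triggered mask separately from the frames of each
#' gaze bin, with shared shuffle settings, restricted to one base image.
#'
#' @param session a bubble [SessionLog].
#' @param partition output of [binByGaze()].
#' @param imageId base image to analyze; default the session's first.
#' @param window response window in ms.
#' @param alpha,nShuffles passed to [computeSTM()].
#' @param minFrames minimum frames per bin to attempt a mask.
#' @param seed optional integer seed shared across bins.
#' @return a [GazeBinnedSTM].
#' @export
conditionalSTMs <- function(session, partition, imageId = NULL,
                            window = c(50, 150), alpha = 0.01,
                            nShuffles = 1000, minFrames = 100,
                            seed = NULL) {
  f <- frames(session)
  if (is.null(imageId)) imageId <- f$image_id[1]
  resp <- computeFrameResponses(session, window)
  nBins <- length(partition$bins)
  stms <- vector("list", nBins)
  valid <- logical(nBins)
  counts <- numeric(nBins)
  for (b in seq_len(nBins)) {
    idx <- partition$bins[[b]]
    idx <- idx[f$image_id[idx] == imageId]
    counts[b] <- length(idx)
    if (!partition$valid[b] || length(idx) < minFrames) next
    M <- sessionMaskMatrix(session, idx)
    stms[[b]] <- computeSTM(M, resp$w[idx], imageId = imageId,
                            alpha = alpha, nShuffles = nShuffles,
                            minFrames = minFrames, seed = seed)
    valid[b] <- stms[[b]]@valid && !any(is.na(stmCentroid(stms[[b]])))
  }
  methods::new("GazeBinnedSTM", binEdges = partition$edges,
               binMeans = partition$means, stms = stms, counts = counts,
               valid = valid)
}

#' Translation-invariance slope of gaze-binned masks
#'
#' Ordinary least squares of the vertical excitatory-centroid coordinate
#' (converted to degrees) on the per-bin mean modal eye position. A slope
#' of 1 indicates a translation-sensitive (retinotopic) driving feature
#' that follows gaze; 0 indicates translation invariance (head-centered).
#' Requires at least 3 valid bins.
#'
#' @param binned a [GazeBinnedSTM].
#' @param degPerPxVal degrees per pixel of the mask raster.
#' @return list with \code{slope}, \code{intercept}, \code{nPoints},
#'   \code{valid}, and the per-bin \code{x} (gaze, deg) and \code{y}
#'   (centroid, deg) points.
#' @export
invarianceSlope <- function(binned, degPerPxVal) {
  ok <- binned@valid
  x <- binned@binMeans[ok]
  y <- vapply(binned@stms[ok], function(s) stmCentroid(s)[["y"]],
              numeric(1)) * degPerPxVal
  if (sum(ok) < 3)
    return(list(slope = NA_real_, intercept = NA_real_,
                nPoints = sum(ok), valid = FALSE, x = x, y = y))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       nPoints = sum(ok), valid = is.finite(stats::coef(fit)[2]),
       x = x, y = y)
}

#' Population tests on translation-invariance slopes
#'
#' Descriptive statistics plus one-tailed t tests of the per-mask slope
#' distribution against 1 (translation sensitive; alternative: mean < 1)
#' and against 0 (alternative: mean > 0), the same tests on per-neuron
#' averaged slopes, and the Pearson correlation between each neuron's
#' average slope and its CRF radius when radii are supplied.
#'
#' @param slopes data.frame with columns \code{neuron}, \code{slope},
#'   optionally \code{crfRadiusDeg}.
#' @param minSlopes minimum number of valid slopes for the t tests;
#'   default 5 (below it only descriptive statistics are returned).
#' @return list with \code{n}, \code{mean}, \code{sd}, \code{tVs1},
#'   \code{tVs0}, \code{perNeuron} (same fields on neuron-averaged
#'   slopes), \code{corRadius} (estimate + p, or NULL).
#' @export
populationSlopeTests <- function(slopes, minSlopes = 5) {
  s <- slopes$slope[is.finite(slopes$slope)]
  out <- list(n = length(s), mean = mean(s), sd = stats::sd(s),
              tVs1 = NULL, tVs0 = NULL, perNeuron = NULL,
              corRadius = NULL)
  tt <- function(v, mu, alt) {
    r <- stats::t.test(v, mu = mu, alternative = alt)
    list(statistic = unname(r$statistic), p = r$p.value, mu = mu,
         alternative = alt)
  }
  if (length(s) >= minSlopes && stats::sd(s) > 0) {
    out$tVs1 <- tt(s, 1, "less")
    out$tVs0 <- tt(s, 0, "greater")
  }
  keep <- is.finite(slopes$slope)
  if (any(keep)) {
    avg <- tapply(slopes$slope[keep], slopes$neuron[keep], mean)
    pn <- list(n = length(avg), mean = mean(avg), sd = stats::sd(avg),
               tVs1 = NULL, tVs0 = NULL)
    if (length(avg) >= minSlopes && stats::sd(avg) > 0) {
      pn$tVs1 <- tt(avg, 1, "less")
      pn$tVs0 <- tt(avg, 0, "greater")
    }
    out$perNeuron <- pn
    if ("crfRadiusDeg" %in% names(slopes)) {
      rad <- tapply(slopes$crfRadiusDeg[keep], slopes$neuron[keep],
                    mean)
      if (length(avg) >= minSlopes && stats::sd(rad) > 0) {
        ct <- stats::cor.test(as.numeric(avg), as.numeric(rad))
        out$corRadius <- list(estimate = unname(ct$estimate),
                              p = ct$p.value)
      }
    }
  }
  out
}
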