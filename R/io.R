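# Plain-text (CSV/JSON) and PNG serialization of the core objects. Bubble
# masks are stored as window centers only; transparency fields are
# recomputed on load, which is deterministic given the combination rule.

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a base image as 8-bit grayscale PNG with a JSON sidecar
#'
#' @param image a [BaseImage].
#' @param path output PNG path; the sidecar is written to
#'   \code{<path>.json}.
#' @return invisibly, the PNG path.
#' @export
writeBaseImage <- function(image, path) {
  png::writePNG(pixels(image), path)
  jsonlite::write_json(list(id = image@id, deg_per_px = image@degPerPx),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a base image written by [writeBaseImage()]
#'
#' @param path PNG path with a \code{<path>.json} sidecar.
#' @return a [BaseImage].
#' @export
readBaseImage <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  methods::new("BaseImage", id = side$id, pixels = px,
               degPerPx = side$deg_per_px)
}

#' Write bubble-window centers of a session to CSV
#'
#' One row per window: \code{frame_id}, \code{window_index}, \code{x_px},
#' \code{y_px}, with full floating-point precision so the transparency
#' fields recompute bit-exactly.
#'
#' @param session a bubble [SessionLog] (or a list of center matrices).
#' @param file output CSV path.
#' @return invisibly, the path.
#' @export
writeMaskCenters <- function(session, file) {
  centers <- if (methods::is(session, "SessionLog"))
    session@maskCenters else session
  rows <- lapply(seq_along(centers), function(i) {
    m <- centers[[i]]
    if (!nrow(m)) return(NULL)
    data.frame(frame_id = i, window_index = seq_len(nrow(m)),
               x_px = fmtNum(m[, 1]), y_px = fmtNum(m[, 2]))
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Read bubble-window centers from CSV
#'
#' @param file CSV written by [writeMaskCenters()].
#' @param nFrames total frame count (frames without windows are empty).
#' @return list of n x 2 center matrices, one per frame.
#' @export
readMaskCenters <- function(file, nFrames = NULL) {
  d <- utils::read.csv(file)
  if (is.null(nFrames)) nFrames <- max(d$frame_id)
  out <- replicate(nFrames, matrix(numeric(0), 0, 2), simplify = FALSE)
  for (fid in unique(d$frame_id)) {
    sub <- d[d$frame_id == fid, ]
    sub <- sub[order(sub$window_index), ]
    out[[fid]] <- cbind(x = as.numeric(sub$x_px), y = as.numeric(sub$y_px))
  }
  out
}

#' Serialize a session log to a CSV/JSON bundle
#'
#' Writes \code{frames.csv}, \code{spikes.csv}, \code{centers.csv} (bubble
#' sessions), \code{meta.json} and the base images (PNG + sidecar) into a
#' directory.
#'
#' @param session a [SessionLog].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeSessionLog <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(frames(session), file.path(dir, "frames.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(t_ms = fmtNum(spikes(session))),
                   file.path(dir, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  if (length(session@maskCenters))
    writeMaskCenters(session, file.path(dir, "centers.csv"))
  jsonlite::write_json(session@meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (img in session@baseImages)
    writeBaseImage(img, file.path(dir, paste0("image_", img@id, ".png")))
  invisible(dir)
}

#' Read a session log bundle written by [writeSessionLog()]
#'
#' @param dir bundle directory.
#' @return a [SessionLog].
#' @export
readSessionLog <- function(dir) {
  framesDf <- utils::read.csv(file.path(dir, "frames.csv"))
  spk <- as.numeric(utils::read.csv(file.path(dir, "spikes.csv"))$t_ms)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ctrFile <- file.path(dir, "centers.csv")
  centersL <- if (file.exists(ctrFile))
    readMaskCenters(ctrFile, nrow(framesDf)) else list()
  imgs <- list()
  for (p in list.files(dir, pattern = "^image_.*\\.png$",
                       full.names = TRUE)) {
    img <- readBaseImage(p)
    imgs[[img@id]] <- img
  }
  methods::new("SessionLog", frames = framesDf, spikes = spk,
               maskCenters = centersL, baseImages = imgs, meta = meta)
}

#' Serialize an SRF to JSON
#'
#' @param srf an [SRF].
#' @param file output JSON path.
#' @return invisibly, the path.
#' @export
writeSRF <- function(srf, file) {
  jsonlite::write_json(
    list(orientations = srf@orientations, spatialFreqs = srf@spatialFreqs,
         phases = srf@phases, R = as.vector(srf@R), dimR = dim(srf@R),
         tensor = as.vector(srf@tensor), dimTensor = dim(srf@tensor),
         counts = as.vector(srf@counts)),
    file, digits = NA, na = "null")
  invisible(file)
}

#' Read an SRF written by [writeSRF()]
#'
#' @param file JSON path.
#' @return an [SRF].
#' @export
readSRF <- function(file) {
  d <- jsonlite::read_json(file, simplifyVector = TRUE)
  methods::new("SRF", orientations = d$orientations,
               spatialFreqs = d$spatialFreqs, phases = d$phases,
               R = matrix(d$R, d$dimR[1], d$dimR[2]),
               tensor = array(d$tensor, d$dimTensor),
               counts = array(d$counts, d$dimTensor))
}

#' Serialize a spatial RF summary to JSON
#'
#' @param rf a [SpatialRF].
#' @param file output JSON path.
#' @return invisibly, the path.
#' @export
writeSpatialRF <- function(rf, file) {
  jsonlite::write_json(
    list(center_deg = rf@centerDeg, radius_deg = rf@radiusDeg,
         grid_x_deg = rf@gridXDeg, grid_y_deg = rf@gridYDeg,
         map = as.vector(rf@map), dim_map = dim(rf@map)),
    file, digits = NA)
  invisible(file)
}

#' Render a spatial-RF response map as a grayscale PNG heatmap
#'
#' @param rf a [SpatialRF].
#' @param file output PNG path.
#' @return invisibly, the path.
#' @export
plotSpatialRFMap <- function(rf, file) {
  m <- rf@map
  rng <- range(m)
  png::writePNG(if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0,
                file)
  invisible(file)
}

#' Serialize a predicted mask to CSV + JSON
#'
#' Writes \code{<base>_excit.csv} and \code{<base>_suppr.csv} (0/1
#' matrices) and \code{<base>_meta.json}.
#'
#' @param pm a [PredictedMask].
#' @param base output path prefix.
#' @return invisibly, \code{base}.
#' @export
writePredictedMask <- function(pm, base) {
  utils::write.table(pm@excit + 0, paste0(base, "_excit.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(pm@suppr + 0, paste0(base, "_suppr.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(image_id = pm@imageId,
                            threshold = pm@threshold,
                            n_excit = sum(pm@excit),
                            n_suppr = sum(pm@suppr)),
                       paste0(base, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' Render a red/blue overlay of a predicted mask
#'
#' @param image the underlying [BaseImage] (or matrix).
#' @param pm a [PredictedMask].
#' @param file output PNG path.
#' @param alphaBlend tint strength; default 0.6.
#' @return invisibly, the path.
#' @export
plotPredictedOverlay <- function(image, pm, file, alphaBlend = 0.6) {
  lab <- matrix(0L, nrow(pm@excit), ncol(pm@excit))
  lab[pm@suppr] <- -1L
  lab[pm@excit] <- 1L  # overlapping pixels shown as excitatory
  stm <- methods::new("SpikeTriggeredMask", imageId = pm@imageId,
                      weights = lab + 0, labels = lab,
                      area = sum(lab != 0),
                      centroid = c(NA_real_, NA_real_),
                      valid = any(lab != 0), meta = list())
  plotSTMOverlay(image, stm, file, alphaBlend)
}

#' Serialize a spike-triggered mask to CSV + JSON
#'
#' Writes \code{<base>_weights.csv}, \code{<base>_labels.csv} and
#' \code{<base>_meta.json}.
#'
#' @param stm a [SpikeTriggeredMask].
#' @param base output path prefix.
#' @return invisibly, \code{base}.
#' @export
writeSTM <- function(stm, base) {
  utils::write.table(stmWeights(stm), paste0(base, "_weights.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(stmLabels(stm), paste0(base, "_labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    c(list(image_id = stm@imageId, area = stm@area,
           centroid = as.numeric(stm@centroid), valid = stm@valid),
      stm@meta),
    paste0(base, "_meta.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(base)
}

#' Render a red/blue overlay of a spike-triggered mask
#'
#' Writes a PNG of the base image with excitatory pixels tinted red and
#' suppressive pixels blue.
#'
#' @param image the underlying [BaseImage] (or matrix).
#' @param stm a [SpikeTriggeredMask].
#' @param file output PNG path.
#' @param alphaBlend tint strength in \code{[0, 1]}; default 0.6.
#' @return invisibly, the path.
#' @export
plotSTMOverlay <- function(image, stm, file, alphaBlend = 0.6) {
  px <- if (methods::is(image, "BaseImage")) pixels(image) else image
  lab <- stmLabels(stm)
  rgb <- array(rep(px, 3), c(dim(px), 3))
  e <- lab == 1; s <- lab == -1
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  r[e] <- (1 - alphaBlend) * r[e] + alphaBlend
  g[e | s] <- (1 - alphaBlend) * g[e | s]
  b[e] <- (1 - alphaBlend) * b[e]
  b[s] <- (1 - alphaBlend) * b[s] + alphaBlend
  r[s] <- (1 - alphaBlend) * r[s]
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  png::writePNG(rgb, file)
  invisible(file)
}
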