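# Configuration-driven pipeline: simulate -> receptive fields -> masks ->
# prediction -> invariance -> report, plus deterministic demo fixtures.

#' Default run configuration
#'
#' Stimulus and analysis defaults match the reference protocol: 20 bubble
#' windows of sigma 7 px on a 128 px raster at 4.25 Hz (240 ms frames),
#' 10 Hz gratings, a 50-150 ms response window for masks, SRF latency
#' 50 ms with a 100 ms integration window, two-tailed alpha 0.01 with the
#' shuffle null, four gaze bins, and the 90th similarity percentile.
#'
#' @param ... named overrides of top-level or nested fields, e.g.
#'   \code{size = 64}, \code{sim = list(nBubbleFrames = 500)}.
#' @return a nested configuration list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    seed = 1,
    size = 128,
    degPerPx = 1 / 48,
    stimulus = list(nWindows = 20, sigma = 7, frameRateHz = 4.25,
                    gratingRateHz = 10, contrast = 1),
    analysis = list(srfLatencyMs = 50, srfWindowMs = 100,
                    stmWindowMs = c(50, 150), alpha = 0.01,
                    nShuffles = 1000, nBins = 4, minBinFrames = 100,
                    percentile = 90, minFrames = 50),
    sim = list(nBubbleFrames = 2000, nGratingFrames = 4000,
               nBaseImages = 2, eyeSdDeg = 0.3,
               neurons = c("linear", "conjunction", "headcentered")))
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Validate a run configuration
#'
#' @param cfg configuration list.
#' @return invisibly TRUE; errors on invalid settings.
#' @export
validateRunConfig <- function(cfg) {
  a <- cfg$analysis
  if (is.null(a$alpha) || a$alpha <= 0 || a$alpha > 1)
    stop("config: alpha must be in (0, 1]")
  if (cfg$stimulus$sigma <= 0) stop("config: sigma must be positive")
  if (cfg$stimulus$nWindows < 0)
    stop("config: nWindows must be non-negative")
  if (cfg$size < 32) stop("config: size must be >= 32")
  if (a$nShuffles < 200) stop("config: nShuffles must be >= 200")
  if (diff(a$stmWindowMs) <= 0) stop("config: empty response window")
  invisible(TRUE)
}

#' Round-trip a configuration through YAML
#'
#' @param cfg configuration list.
#' @param file YAML path.
#' @return [readRunConfig()] returns the configuration list.
#' @export
writeRunConfig <- function(cfg, file) {
  yaml::write_yaml(cfg, file, precision = 15)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) yaml::read_yaml(file)

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

# Build the demo neuron set for a config: a quasi-linear cell, a
# feature-conjunction cell with tuned suppression (retinotopic), and a
# head-centered template cell.
demoNeurons <- function(cfg, baseImages) {
  size <- cfg$size
  dpp <- cfg$degPerPx
  nyq <- 0.5 / dpp
  oris <- seq(0, 157.5, by = 22.5)
  sfs <- nyq / 2^(4:1)
  img1 <- baseImages[[1]]
  ctr <- size / 2
  tplE <- templateFromImage(img1, c(ctr - size %/% 6, ctr), 15, 1)
  tplS <- templateFromImage(img1, c(ctr + size %/% 6, ctr), 15, -0.8)
  list(
    linear = modelNeuron(
      id = "linear", size = size, degPerPx = dpp,
      srfGain = gaussianSRF(oris, sfs, 45, sfs[2]),
      orientations = oris, spatialFreqs = sfs, positionCoding = 0,
      threshold = 0.05, gain = 120, baseline = 2),
    conjunction = modelNeuron(
      id = "conjunction", size = size, degPerPx = dpp,
      srfGain = gaussianSRF(oris, sfs, 90, sfs[2], floor = 0.6),
      orientations = oris, spatialFreqs = sfs,
      templates = list(excit = tplE, suppr = tplS),
      positionCoding = 0, threshold = -0.2, gain = 80, baseline = 2),
    headcentered = modelNeuron(
      id = "headcentered", size = size, degPerPx = dpp,
      templates = list(excit = tplE, suppr = tplS),
      positionCoding = 1, threshold = -0.2, gain = 80, baseline = 2))
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Executes simulate -> SRF / spatial RF estimation -> spike-triggered
#' masks -> linear-model prediction -> similarity and invariance analyses
#' -> report, writing CSV tables, JSON summaries and PNG overlays to
#' \code{outdir}. Deterministic given \code{cfg$seed}.
#'
#' @param cfg configuration from [defaultRunConfig()].
#' @param outdir output directory.
#' @return invisibly, a list with the per-neuron results and the paths of
#'   the written tables.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outdir = tempfile()) {
  validateRunConfig(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  a <- cfg$analysis
  st <- cfg$stimulus
  baseImages <- withStage("stimuli", lapply(
    seq_len(cfg$sim$nBaseImages), function(i)
      generateBaseImage(cfg$size, 1, cfg$degPerPx, id = paste0("img", i),
                        seed = cfg$seed * 1000 + i)))
  neurons <- withStage("neurons", demoNeurons(cfg, baseImages))
  stmRows <- list(); scoreRows <- list(); slopeRows <- list()
  results <- list()
  for (nm in intersect(cfg$sim$neurons, names(neurons))) {
    neuron <- neurons[[nm]]
    res <- list()
    res$gratings <- withStage("simulate-gratings", simulateGratingSession(
      neuron, seq(0, 157.5, by = 22.5),
      (0.5 / cfg$degPerPx) / 2^(4:1), c(0, 90, 180, 270),
      cfg$sim$nGratingFrames, contrast = st$contrast,
      frameMs = 1000 / st$gratingRateHz, seed = cfg$seed + 11))
    res$srf <- withStage("srf", estimateSRF(
      res$gratings, a$srfLatencyMs, a$srfWindowMs))
    grid <- round(seq(cfg$size * 0.15, cfg$size * 0.85, length.out = 8))
    res$probes <- withStage("simulate-probes", simulateProbeSession(
      neuron, grid, grid, probeSizePx = max(3, cfg$size %/% 16),
      repeats = 8, seed = cfg$seed + 13))
    res$spatialRF <- withStage("spatial-rf", tryCatch(
      estimateSpatialRF(res$probes),
      error = function(e) NULL))
    eye <- makeEyeTrace(cfg$sim$nBubbleFrames, cfg$sim$eyeSdDeg,
                        frameMs = 1000 / st$frameRateHz,
                        seed = cfg$seed + 17)
    res$bubbles <- withStage("simulate-bubbles", simulateBubbleSession(
      neuron, baseImages, cfg$sim$nBubbleFrames, eyeTrace = eye,
      nWindows = st$nWindows, sigma = st$sigma,
      frameMs = 1000 / st$frameRateHz, seed = cfg$seed + 19))
    res$stms <- withStage("stm", sessionSTMs(
      res$bubbles, a$stmWindowMs, a$alpha, a$nShuffles, a$minFrames,
      seed = cfg$seed + 23))
    resp <- computeFrameResponses(res$bubbles, a$stmWindowMs)
    f <- frames(res$bubbles)
    res$scores <- list(); res$similarity <- list()
    for (id in names(res$stms)) {
      stm <- res$stms[[id]]
      if (!stm@valid) next
      img <- res$bubbles@baseImages[[id]]
      crfDeg <- if (!is.null(res$spatialRF)) res$spatialRF@radiusDeg else
        neuron@crfRadiusPx * cfg$degPerPx
      mm <- maskMetrics(stm, crfDeg, cfg$degPerPx)
      stmRows[[length(stmRows) + 1]] <- data.frame(
        neuron = nm, image = id, valid = stm@valid, area_px = mm$areaPx,
        area_fraction_crf = mm$areaFractionOfCRF,
        centroid_x = stm@centroid[1], centroid_y = stm@centroid[2],
        outside_crf = mm$crfOutsideFlag)
      idx <- which(f$image_id == id)
      M <- sessionMaskMatrix(res$bubbles, idx)
      unmasked <- driveRate(neuron, pixels(img), c(0, 0), id)
      res$similarity[[id]] <- withStage("similarity", similarityAnalysis(
        stm, M, resp$w[idx], unmaskedRate = unmasked,
        q = a$percentile))
      if (sum(stmLabels(stm) == 1) >= 1) {
        pred <- withStage("predict", predictMasks(
          img, res$srf, max(1, sum(stmLabels(stm) == 1)), cfg$degPerPx))
        sc <- scorePrediction(pred, stm)
        sc$neuron <- nm; sc$image <- id
        scoreRows[[length(scoreRows) + 1]] <- sc
        writeSTM(stm, file.path(outdir, paste0(nm, "_", id)))
        plotSTMOverlay(img, stm,
                       file.path(outdir, paste0(nm, "_", id, ".png")))
      }
      part <- withStage("invariance", tryCatch(
        binByGaze(res$bubbles, a$nBins, a$minBinFrames),
        error = function(e) NULL))
      if (!is.null(part)) {
        gb <- conditionalSTMs(res$bubbles, part, id, a$stmWindowMs,
                              a$alpha, a$nShuffles,
                              minFrames = a$minBinFrames,
                              seed = cfg$seed + 29)
        sl <- invarianceSlope(gb, cfg$degPerPx)
        slopeRows[[length(slopeRows) + 1]] <- data.frame(
          neuron = nm, image = id, slope = sl$slope,
          n_bins = sl$nPoints, valid = sl$valid,
          crfRadiusDeg = crfDeg)
      }
    }
    results[[nm]] <- res
  }
  stmTab <- do.call(rbind, stmRows)
  scoreTab <- do.call(rbind, scoreRows)
  slopeTab <- do.call(rbind, slopeRows)
  utils::write.csv(stmTab, file.path(outdir, "stms.csv"),
                   row.names = FALSE)
  if (!is.null(scoreTab))
    utils::write.csv(scoreTab, file.path(outdir, "scores.csv"),
                     row.names = FALSE)
  if (!is.null(slopeTab))
    utils::write.csv(slopeTab, file.path(outdir, "slopes.csv"),
                     row.names = FALSE)
  report <- withStage("report", pipelineReport(stmTab, scoreTab,
                                               slopeTab))
  jsonlite::write_json(report, file.path(outdir, "population.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  jsonlite::write_json(
    list(config = cfg, package_version =
           as.character(utils::packageVersion("bubbleSTM"))),
    file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, stms = stmTab, scores = scoreTab,
                 slopes = slopeTab, report = report, outdir = outdir))
}

# Population statistics: Wilcoxon signed-rank of mask area fraction
# against the CRF (< 1), sign test of excitatory vs suppressive
# prediction overlap, and the invariance t tests.
pipelineReport <- function(stmTab, scoreTab, slopeTab) {
  rep <- list()
  if (!is.null(stmTab) && nrow(stmTab) >= 3) {
    w <- stats::wilcox.test(stmTab$area_fraction_crf, mu = 1,
                            alternative = "less")
    rep$maskVsCRF <- list(mean_fraction = mean(stmTab$area_fraction_crf),
                          p = w$p.value)
  }
  if (!is.null(scoreTab)) {
    e <- scoreTab$overlapPct[scoreTab$component == "excit"]
    s <- scoreTab$overlapPct[scoreTab$component == "suppr"]
    ok <- is.finite(e) & is.finite(s) & e != s
    if (sum(ok) >= 3) {
      b <- stats::binom.test(sum(e[ok] > s[ok]), sum(ok))
      rep$excitVsSuppr <- list(mean_excit = mean(e, na.rm = TRUE),
                               mean_suppr = mean(s, na.rm = TRUE),
                               p_sign = b$p.value)
    }
  }
  if (!is.null(slopeTab) && any(slopeTab$valid, na.rm = TRUE))
    rep$invariance <- populationSlopeTests(
      slopeTab[slopeTab$valid %in% TRUE, ])
  rep
}

#' Generate the bundled demo dataset deterministically
#'
#' Writes a small simulated bubble session (64 x 64 rasters, 500 frames,
#' one feature-template neuron) as a CSV/JSON bundle plus an MD5 manifest.
#' Regeneration with the same seed reproduces the committed bytes;
#' [verifyFixtures()] checks the manifest.
#'
#' @param dir output directory.
#' @param seed integer seed; default 1.
#' @return invisibly, \code{dir}.
#' @export
makeFixtures <- function(dir, seed = 1) {
  img <- generateBaseImage(64, 1, 1 / 24, id = "demo", seed = seed)
  tpl <- templateFromImage(img, c(24, 32), 13, 1)
  neuron <- modelNeuron(id = "demo", size = 64, degPerPx = 1 / 24,
                        templates = list(excit = tpl), threshold = 0,
                        gain = 80, baseline = 2)
  ses <- simulateBubbleSession(neuron, img, 500, seed = seed)
  writeSessionLog(ses, dir)
  files <- sort(setdiff(list.files(dir), "MANIFEST.txt"))
  md5 <- tools::md5sum(file.path(dir, files))
  writeLines(paste(unname(md5), files), file.path(dir, "MANIFEST.txt"))
  invisible(dir)
}

#' Verify the demo dataset against its MD5 manifest
#'
#' @param dir fixture directory written by [makeFixtures()].
#' @return TRUE when every file matches its recorded checksum.
#' @export
verifyFixtures <- function(dir) {
  man <- utils::read.table(file.path(dir, "MANIFEST.txt"),
                    col.names = c("md5", "file"),
                    colClasses = "character")
  cur <- tools::md5sum(file.path(dir, man$file))
  all(!is.na(cur) & unname(cur) == man$md5)
}
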