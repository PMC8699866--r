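#' End-to-end pipeline configuration
#'
#' A single global seed fans out to per-stage seeds (seed + fixed stage
#' offsets). The `smoke` profile runs the whole pipeline at desk scale.
#'
#' @param nLvdd,nControl subjects per class.
#' @param duration recording length (s).
#' @param imageSize spectrogram side length.
#' @param ganEpochs,cnnEpochs training epochs.
#' @param folds cross-validation folds.
#' @param coefficient DCGAN expansion coefficient for the CV stage.
#' @param tstrRepeats TSTR repetitions.
#' @param seed global seed.
#' @param smoke apply the desk-scale smoke profile
#'   (4+4 subjects, 30 s, 32x32, 30 GAN epochs, 20 CNN epochs, k = 4).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(nLvdd = 30, nControl = 41, duration = 300,
                           imageSize = 128, ganEpochs = 300,
                           cnnEpochs = 500, folds = 10, coefficient = 8,
                           tstrRepeats = 5, seed = 1L, smoke = FALSE) {
  cfg <- list(nLvdd = nLvdd, nControl = nControl, duration = duration,
              imageSize = imageSize, ganEpochs = ganEpochs,
              cnnEpochs = cnnEpochs, folds = folds,
              coefficient = coefficient, tstrRepeats = tstrRepeats,
              seed = as.integer(seed))
  if (smoke) {
    cfg$nLvdd <- 4; cfg$nControl <- 4; cfg$duration <- 30
    cfg$imageSize <- 32; cfg$ganEpochs <- 30; cfg$cnnEpochs <- 20
    cfg$folds <- 4; cfg$coefficient <- 2; cfg$tstrRepeats <- 1
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a key=value text file
#'
#' Unknown keys raise an error naming the key; missing keys keep defaults.
#'
#' @param path text file with `key = value` lines (`#` comments allowed).
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- pipelineConfig()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (key == "seed") as.integer(val) else as.numeric(val)
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> segment -> frame -> spectrogram -> augment
#' (non-generative + DCGAN) -> subject-wise CV classification -> TSTR ->
#' report. All intermediates are written under `outDir` and listed in a
#' `manifest.json`; the final report is `report.json`/`report.csv`.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory.
#' @param writeAudio write per-subject WAV files (default FALSE to keep
#'   runs light).
#' @return the report list, invisibly.
#' @export
runPipeline <- function(cfg = pipelineConfig(smoke = TRUE), outDir,
                        writeAudio = FALSE) {
  if (!inherits(cfg, "PipelineConfig")) stop("cfg must be a PipelineConfig")
  for (key in c("nLvdd", "nControl", "duration", "imageSize", "ganEpochs",
                "cnnEpochs", "folds", "coefficient", "tstrRepeats",
                "seed")) {
    if (is.null(cfg[[key]])) stop("config missing stage key: ", key)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(p) written <<- c(written, p)

  # stage seeds fan out from the global seed
  seeds <- cfg$seed + c(sim = 101L, gan = 202L, cnn = 303L, cv = 404L,
                        tstr = 505L)

  simCfg <- pcgSimConfig(duration = cfg$duration, noiseSnr = 25)
  cohort <- simulateCohort(cfg$nLvdd, cfg$nControl, simCfg,
                           seed = seeds["sim"])
  if (writeAudio) {
    writeCohort(cohort, file.path(outDir, "audio"))
    note(file.path(outDir, "audio", "manifest.csv"))
  }

  prep <- lapply(cohort, preprocessRecording)
  segmenter <- trainSegmenter(prep[seq_len(min(6, length(prep)))])

  frames <- list()
  boundaries <- list()
  for (r in prep) {
    st <- segmentStates(r, segmenter)
    frames <- c(frames, extractFrames(r, st))
    ends <- cumsum(st@lengths)
    boundaries[[length(boundaries) + 1]] <-
      data.frame(subject_id = r@subjectId, state = st@states,
                 start_sample = ends - st@lengths + 1L, end_sample = ends)
  }
  bpath <- file.path(outDir, "boundaries.csv")
  write.csv(do.call(rbind, boundaries), bpath, row.names = FALSE)
  note(bpath)
  if (length(frames) == 0) stop("stage segment: no frames extracted")

  spCfg <- spectrogramConfig(outputSize = c(cfg$imageSize, cfg$imageSize),
                             hop = if (cfg$imageSize < 128) 32 else 10)
  real <- framesToSpectrograms(frames, spCfg)
  idxPath <- file.path(outDir, "images.csv")
  write.csv(imageInfo(real), idxPath, row.names = FALSE)
  note(idxPath)

  ng <- augmentNonGenerativeDataset(frames, spectroCfg = spCfg)

  info <- imageInfo(real)
  generators <- list()
  for (cl in .lvddClasses) {
    sub <- subsetImages(real, info$classLabel == cl)
    gcfg <- ganConfig(imageSize = cfg$imageSize, epochs = cfg$ganEpochs,
                      batchSize = min(32, nImages(sub)),
                      seed = seeds["gan"] + match(cl, .lvddClasses))
    generators[[cl]] <- trainDCGAN(sub, gcfg)$generator
  }
  gen <- expandDataset(real, generators, cfg$coefficient,
                       seed = seeds["gan"])

  plan <- makeCVPlan(real, k = cfg$folds, seed = seeds["cv"])
  cnnCfg <- cnnConfig(inputSize = cfg$imageSize, epochs = cfg$cnnEpochs,
                      seed = seeds["cnn"])
  cvRS <- runCrossValidation(real, NULL, cnnCfg, plan)
  cvGAN <- runCrossValidation(real, gen, cnnCfg, plan)

  tstr <- similarityTSTR(gen, real, cnnCfg, repeats = cfg$tstrRepeats,
                         seed = seeds["tstr"])

  nL <- sum(info$classLabel == "lvdd")
  nC <- sum(info$classLabel == "control")
  report <- list(
    config = unclass(cfg),
    datasetSizes = datasetSizes(nL, nC, coefficient = cfg$coefficient),
    cvRealOnly = cvRS$summary,
    cvWithDCGAN = cvGAN$summary,
    tstrAccuracy = round(tstr$accuracy, 6),
    nFrames = length(frames),
    nGenerated = nImages(gen))
  paths <- writeReport(report, outDir)
  note(paths)

  manifest <- file.path(outDir, "manifest.json")
  writeLines(jsonlite::toJSON(sort(unname(written)), pretty = TRUE),
             manifest)
  invisible(report)
}
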