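#' Train-on-generated / test-on-real similarity (TSTR)
#'
#' Trains the CNN only on generated images and evaluates it on the real
#' set; the resulting test accuracy reflects how much of the real class
#' structure the generated samples carry. Repeated with different training
#' seeds; the mean is returned.
#'
#' @param generated a [SpectrogramSet-class] containing both classes.
#' @param real a [SpectrogramSet-class] of real images.
#' @param cfg a [cnnConfig()].
#' @param repeats number of repetitions (default 5).
#' @param seed base seed; repetition `i` trains with `seed + i`.
#' @return list with `accuracy` (mean), `perRun` (vector) and `n` sizes.
#' @export
similarityTSTR <- function(generated, real, cfg = cnnConfig(),
                           repeats = 5, seed = 1L) {
  gi <- imageInfo(generated)
  if (length(intersect(.lvddClasses, unique(gi$classLabel))) < 2)
    stop("generated set must contain both classes")
  accs <- numeric(repeats)
  for (i in seq_len(repeats)) {
    cfgI <- cfg
    cfgI$seed <- as.integer(seed + i)
    fit <- trainCNN(generated, val = NULL, cfg = cfgI)$model
    pred <- predictCNN(fit, real)
    accs[i] <- mean(pred$labels == imageInfo(real)$classLabel)
  }
  list(accuracy = mean(accs), perRun = accs,
       n = c(generated = nImages(generated), real = nImages(real)))
}

#' Expansion-coefficient sweep
#'
#' For each coefficient `k`, augments the training folds with `k` generated
#' images per real image (per class) and runs the subject-wise
#' cross-validation.
#'
#' @param real a [SpectrogramSet-class] of real images.
#' @param generators named list of per-class [GANGenerator-class] objects,
#'   or a function `f(class, n, seed)` returning a SpectrogramSet (used for
#'   stubbed sweeps).
#' @param coefficients ascending non-negative integers.
#' @param cfg a [cnnConfig()].
#' @param plan a [CVPlan-class].
#' @param seed seed for generation.
#' @param ... passed to [runCrossValidation()] (e.g. a stub trainer).
#' @return data.frame with one row per coefficient and metric summary
#'   columns.
#' @export
expansionSweep <- function(real, generators, coefficients, cfg = cnnConfig(),
                           plan, seed = 1L, ...) {
  if (length(coefficients) == 0) stop("empty coefficient list")
  if (is.unsorted(coefficients)) stop("coefficients must be ascending")
  if (any(coefficients < 0)) stop("coefficients must be non-negative")
  rows <- list()
  for (k in coefficients) {
    extra <- if (k == 0) NULL
             else if (is.function(generators)) {
               info <- imageInfo(real)
               sets <- lapply(intersect(.lvddClasses, info$classLabel),
                              function(cl) generators(cl,
                                k * sum(info$classLabel == cl), seed))
               do.call(bindSpectrogramSets, sets)
             } else expandDataset(real, generators, k, seed = seed)
    res <- runCrossValidation(real, extra, cfg, plan, ...)
    s <- res$summary
    rows[[length(rows) + 1]] <- data.frame(
      coefficient = k,
      nGenerated = if (is.null(extra)) 0L else nImages(extra),
      accMean = s$mean[s$metric == "accuracy"],
      accSd = s$sd[s$metric == "accuracy"],
      seMean = s$mean[s$metric == "sensitivity"],
      spMean = s$mean[s$metric == "specificity"])
  }
  do.call(rbind, rows)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) two-sample t-test computed from group means,
#' standard deviations and sizes, with `df = nA + nB - 2`; the Welch form
#' is available via `welch = TRUE`. The pooled form is the default because
#' it reproduces the cohort-table p-values this package mirrors.
#'
#' @param meanA,sdA,nA first group summary.
#' @param meanB,sdB,nB second group summary.
#' @param welch use the Welch unequal-variance form.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
summaryTTest <- function(meanA, sdA, nA, meanB, sdB, nB, welch = FALSE) {
  if (nA < 2 || nB < 2) stop("each group needs n >= 2")
  if (sdA < 0 || sdB < 0) stop("standard deviations must be non-negative")
  if (welch) {
    se2a <- sdA^2 / nA; se2b <- sdB^2 / nB
    t <- (meanA - meanB) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (nA - 1) + se2b^2 / (nB - 1))
  } else {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    t <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Dataset bookkeeping for the augmentation protocol
#'
#' Image counts per class for the real-sample (RS) dataset, the
#' non-generative (NG) dataset (5 augmented images per frame), the DCGAN
#' dataset (`coefficient` generated images per real one) and the combined
#' training sets.
#'
#' @param nLvdd,nControl real frame counts per class (the emulated cohort
#'   has 3677 and 4803).
#' @param ngFactor augmented images per frame (5 techniques).
#' @param coefficient DCGAN expansion coefficient (default 8).
#' @return data.frame of per-class counts by dataset.
#' @export
datasetSizes <- function(nLvdd = 3677, nControl = 4803, ngFactor = 5,
                         coefficient = 8) {
  data.frame(
    dataset = c("RS", "NG", "DCGAN", "RS+NG", "RS+DCGAN"),
    lvdd = c(nLvdd, ngFactor * nLvdd, coefficient * nLvdd,
             (1 + ngFactor) * nLvdd, (1 + coefficient) * nLvdd),
    control = c(nControl, ngFactor * nControl, coefficient * nControl,
                (1 + ngFactor) * nControl, (1 + coefficient) * nControl))
}

#' Write evaluation results as reproducible JSON and CSV reports
#'
#' JSON is written with sorted keys and a fixed numeric format, so
#' identical inputs produce byte-identical files.
#'
#' @param results named list of evaluation outputs (data.frames, lists,
#'   scalars).
#' @param dir output directory.
#' @param name base file name.
#' @return paths of the written files, invisibly.
#' @export
writeReport <- function(results, dir, name = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(dir, paste0(name, ".json"))
  csvPath <- file.path(dir, paste0(name, ".csv"))
  roundNum <- function(x) {
    if (is.list(x)) lapply(x, roundNum)
    else if (is.data.frame(x)) as.data.frame(lapply(x, roundNum))
    else if (is.numeric(x)) round(x, 6)
    else x
  }
  json <- jsonlite::toJSON(roundNum(results), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, jsonPath)
  flat <- results[vapply(results, is.data.frame, logical(1))]
  if (length(flat) > 0) {
    rows <- do.call(rbind, lapply(names(flat), function(nm) {
      df <- flat[[nm]]
      data.frame(table = nm, row = seq_len(nrow(df)),
                 field = rep(names(df), each = nrow(df)),
                 value = unlist(lapply(df, function(col)
                   as.character(col)), use.names = FALSE))
    }))
    write.csv(rows, csvPath, row.names = FALSE)
  } else {
    write.csv(data.frame(), csvPath, row.names = FALSE)
  }
  invisible(c(json = jsonPath, csv = csvPath))
}
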