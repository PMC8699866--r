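#' PCGRecording: a mono heart-sound recording
#'
#' Amplitude series with its sampling rate, subject identifier and optional
#' cohort label (`"lvdd"` or `"control"`). The unit flowing through
#' preprocessing and segmentation.
#'
#' @slot samples numeric amplitude series.
#' @slot samplingRate sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot classLabel `"lvdd"`, `"control"` or `NA`.
#' @export
setClass("PCGRecording",
  representation(samples = "numeric", samplingRate = "numeric",
                 subjectId = "character", classLabel = "character"),
  prototype(subjectId = NA_character_, classLabel = NA_character_),
  validity = function(object) {
    if (length(object@samples) < 1) return("samples must be non-empty")
    if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
      return("samplingRate must be a single positive number")
    if (!is.na(object@classLabel) && !object@classLabel %in% .lvddClasses)
      return("classLabel must be 'lvdd', 'control' or NA")
    TRUE
  })

#' StateSequence: per-sample heart-sound state labels
#'
#' Run-length encoded labels over the four cardiac states
#' S1 -> systole -> S2 -> diastole, cyclic. Coordinates are 1-based and runs
#' are stored as (state, length) pairs that tile the recording exactly.
#'
#' @slot states character vector of run states.
#' @slot lengths integer run lengths (samples).
#' @slot samplingRate sampling rate in Hz.
#' @export
setClass("StateSequence",
  representation(states = "character", lengths = "integer",
                 samplingRate = "numeric"),
  validity = function(object) {
    if (length(object@states) != length(object@lengths))
      return("states and lengths must have equal length")
    if (any(object@lengths <= 0)) return("all run lengths must be positive")
    bad <- !object@states %in% .pcgStates
    if (any(bad)) return("states must be S1/systole/S2/diastole")
    if (length(object@states) > 1) {
      idx <- match(object@states, .pcgStates)
      step <- diff(idx) %% 4L
      if (any(step != 1L)) return("states must follow the cyclic order")
    }
    TRUE
  })

.pcgStates <- c("S1", "systole", "S2", "diastole")

#' SimulatedPCG: a simulated recording with ground truth
#'
#' Extends [PCGRecording-class] with the true state sequence and the true S1
#' onset sample indices, so segmentation can be scored exactly.
#'
#' @slot trueStates a [StateSequence-class].
#' @slot trueS1Onsets integer sample indices (1-based) of true S1 onsets.
#' @export
setClass("SimulatedPCG", contains = "PCGRecording",
  representation(trueStates = "StateSequence", trueS1Onsets = "integer"),
  validity = function(object) {
    if (sum(object@trueStates@lengths) != length(object@samples))
      return("trueStates must tile the recording exactly")
    if (is.unsorted(object@trueS1Onsets, strictly = TRUE))
      return("trueS1Onsets must be strictly increasing")
    TRUE
  })

#' PCGFrame: a fixed-length analysis frame
#'
#' A 1.6 s window (1600 samples at 1000 Hz) starting at a detected S1 onset.
#'
#' @slot samples numeric amplitudes.
#' @slot startIndex 1-based offset of the first sample in the source
#'   recording.
#' @slot subjectId,classLabel provenance.
#' @export
setClass("PCGFrame",
  representation(samples = "numeric", startIndex = "integer",
                 subjectId = "character", classLabel = "character"),
  prototype(subjectId = NA_character_, classLabel = NA_character_))

#' SpectrogramSet: a set of spectrogram images with provenance
#'
#' Pixel data are stored as a (height, width, 3, n) array in `[0, 1]`;
#' per-image provenance (frame id, subject, class label, origin) lives in the
#' `info` data frame, one row per image.
#'
#' @slot pixels numeric array (h, w, 3, n).
#' @slot info data.frame with columns `frameId`, `subjectId`, `classLabel`,
#'   `origin` (one of `real`, `nongenerative_aug`, `gan_generated`).
#' @export
setClass("SpectrogramSet",
  representation(pixels = "array", info = "data.frame"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 4 || d[3] != 3)
      return("pixels must be a (h, w, 3, n) array")
    if (nrow(object@info) != d[4])
      return("info must have one row per image")
    need <- c("frameId", "subjectId", "classLabel", "origin")
    if (!all(need %in% names(object@info)))
      return(paste("info must have columns:", paste(need, collapse = ", ")))
    if (length(object@pixels) > 0) {
      rng <- range(object@pixels)
      if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        return("pixel values must lie in [0, 1]")
    }
    ok <- object@info$origin %in% c("real", "nongenerative_aug",
                                    "gan_generated")
    if (!all(ok)) return("invalid origin tag")
    TRUE
  })

#' SegmenterModel: trained four-state heart-sound segmenter
#'
#' Multinomial logistic emissions over envelope features plus Gaussian
#' per-state duration models, decoded with a duration-constrained Viterbi
#' pass over the fixed cyclic state order.
#'
#' @slot emission fitted `nnet::multinom` object.
#' @slot durationParams data.frame (state, meanSec, sdSec).
#' @slot featureRate feature frame rate in Hz.
#' @slot meanCycleSec mean cardiac cycle length in seconds.
#' @export
setClass("SegmenterModel",
  representation(emission = "ANY", durationParams = "data.frame",
                 featureRate = "numeric", meanCycleSec = "numeric"))

#' Neural-network parameter containers
#'
#' `CNNModel`, `GANGenerator` and `GANDiscriminator` hold a list of layer
#' parameter objects plus the configuration used to build them. Weights are
#' plain R arrays; use the training and prediction functions rather than the
#' slots.
#'
#' @slot layers list of layer objects.
#' @slot config configuration list.
#' @name nn-classes
NULL

#' @rdname nn-classes
#' @export
setClass("CNNModel", representation(layers = "list", config = "list"))
#' @rdname nn-classes
#' @export
setClass("GANGenerator", representation(layers = "list", config = "list"))
#' @rdname nn-classes
#' @export
setClass("GANDiscriminator", representation(layers = "list", config = "list"))

#' CVPlan: subject-wise k-fold cross-validation plan
#'
#' @slot folds named integer vector: fold index per subject.
#' @slot k number of folds.
#' @slot seed RNG seed used for the assignment.
#' @export
setClass("CVPlan",
  representation(folds = "integer", k = "integer", seed = "integer"),
  validity = function(object) {
    if (is.null(names(object@folds))) return("folds must be named by subject")
    if (anyDuplicated(names(object@folds)))
      return("each subject must appear in exactly one fold")
    if (!all(object@folds %in% seq_len(object@k)))
      return("fold indices must be in 1..k")
    TRUE
  })

setMethod("show", "PCGRecording", function(object) {
  cat(sprintf("%s: %d samples @ %g Hz (%.1f s), subject %s, label %s\n",
              class(object), length(object@samples), object@samplingRate,
              length(object@samples) / object@samplingRate,
              object@subjectId, object@classLabel))
})

setMethod("show", "StateSequence", function(object) {
  cat(sprintf("StateSequence: %d runs, %d samples @ %g Hz (%d cycles)\n",
              length(object@states), sum(object@lengths),
              object@samplingRate, sum(object@states == "S1")))
})

setMethod("show", "SpectrogramSet", function(object) {
  d <- dim(object@pixels)
  tab <- table(object@info$classLabel, object@info$origin)
  cat(sprintf("SpectrogramSet: %d images of %dx%dx3\n", d[4], d[1], d[2]))
  print(tab)
})

setMethod("show", "SegmenterModel", function(object) {
  cat("SegmenterModel (LR-HSMM): multinomial emissions @",
      object@featureRate, "Hz\n")
  print(object@durationParams, row.names = FALSE)
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %d subjects in %d folds (seed %d)\n",
              length(object@folds), object@k, object@seed))
})

#' Construct a PCGRecording
#'
#' @param samples numeric amplitude series.
#' @param samplingRate sampling rate in Hz.
#' @param subjectId subject identifier.
#' @param classLabel `"lvdd"`, `"control"` or `NA`.
#' @return a [PCGRecording-class].
#' @export
PCGRecording <- function(samples, samplingRate, subjectId = NA_character_,
                         classLabel = NA_character_) {
  new("PCGRecording", samples = as.numeric(samples),
      samplingRate = samplingRate, subjectId = as.character(subjectId),
      classLabel = as.character(classLabel))
}

#' Construct a StateSequence from run-length encoding
#'
#' @param states character run states (cyclic S1/systole/S2/diastole order).
#' @param lengths integer run lengths in samples.
#' @param samplingRate sampling rate in Hz.
#' @return a [StateSequence-class].
#' @export
StateSequence <- function(states, lengths, samplingRate) {
  new("StateSequence", states = as.character(states),
      lengths = as.integer(lengths), samplingRate = samplingRate)
}

#' @describeIn StateSequence expand to one label per sample.
#' @param x a StateSequence.
#' @export
stateLabels <- function(x) rep(x@states, x@lengths)

#' @describeIn StateSequence 1-based start indices of S1 runs.
#' @export
s1Onsets <- function(x) {
  starts <- cumsum(c(1L, x@lengths))[seq_along(x@states)]
  starts[x@states == "S1"]
}

#' Accessors for recordings and image sets
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
pcgSamples <- function(x) x@samples
#' @rdname accessors
#' @export
samplingRate <- function(x) x@samplingRate
#' @rdname accessors
#' @export
subjectId <- function(x) x@subjectId
#' @rdname accessors
#' @export
groupLabel <- function(x) x@classLabel
#' @rdname accessors
#' @export
nImages <- function(x) dim(x@pixels)[4]
#' @rdname accessors
#' @export
imageInfo <- function(x) x@info
#' @rdname accessors
#' @param i image index.
#' @export
imageData <- function(x, i) x@pixels[, , , i, drop = FALSE][, , , 1]

#' Build a SpectrogramSet from an array and provenance table
#'
#' @param pixels (h, w, 3, n) array in `[0,1]`.
#' @param info data.frame with columns frameId, subjectId, classLabel, origin.
#' @return a [SpectrogramSet-class].
#' @export
SpectrogramSet <- function(pixels, info) {
  info$subjectId <- as.character(info$subjectId)
  info$frameId <- as.character(info$frameId)
  new("SpectrogramSet", pixels = pixels, info = info)
}

#' Concatenate spectrogram sets
#'
#' @param ... SpectrogramSet objects with identical image dimensions.
#' @return a combined [SpectrogramSet-class].
#' @export
bindSpectrogramSets <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  sets <- sets[vapply(sets, nImages, integer(1)) > 0]
  if (length(sets) == 0) stop("no non-empty sets to bind")
  d <- dim(sets[[1]]@pixels)[1:3]
  for (s in sets) {
    if (!all(dim(s@pixels)[1:3] == d)) stop("image dimensions differ")
  }
  n <- sum(vapply(sets, nImages, integer(1)))
  px <- array(0, c(d, n))
  at <- 1L
  for (s in sets) {
    k <- nImages(s)
    px[, , , at:(at + k - 1L)] <- s@pixels
    at <- at + k
  }
  SpectrogramSet(px, do.call(rbind, lapply(sets, imageInfo)))
}

#' Subset a SpectrogramSet by image index
#'
#' @param x a SpectrogramSet.
#' @param idx integer or logical index over images.
#' @return a [SpectrogramSet-class].
#' @export
subsetImages <- function(x, idx) {
  if (is.logical(idx)) idx <- which(idx)
  SpectrogramSet(x@pixels[, , , idx, drop = FALSE],
                 x@info[idx, , drop = FALSE])
}
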