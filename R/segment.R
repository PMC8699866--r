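# Four-state heart-sound segmentation: envelope features at 50 Hz,
# multinomial logistic emissions, Gaussian state durations, and a
# duration-constrained Viterbi decode over the fixed cyclic order
# S1 -> systole -> S2 -> diastole.

.analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

.lowpass <- function(x, fs, cutoffHz, order = 2) {
  bf <- signal::butter(order, min(cutoffHz / (fs / 2), 0.99))
  signal::filtfilt(bf, x)
}

.bandpass <- function(x, fs, low, high, order = 2) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# mean over consecutive blocks of `step` samples -> feature rate fs/step
.blockMean <- function(x, step) {
  n <- floor(length(x) / step) * step
  colMeans(matrix(x[seq_len(n)], nrow = step))
}

#' Envelope feature matrix for segmentation
#'
#' Four envelopes of the 1000 Hz signal, sampled at a fixed 50 Hz feature
#' rate: homomorphic envelope, analytic (Hilbert) envelope magnitude,
#' 20-200 Hz band power, and a wavelet (level-4 detail) envelope. Each
#' column is z-normalised.
#'
#' @param rec a [PCGRecording-class] at 1000 Hz.
#' @param featureRate output feature rate in Hz (default 50).
#' @return numeric matrix, one row per feature frame.
#' @export
extractEnvelopeFeatures <- function(rec, featureRate = 50) {
  fs <- rec@samplingRate
  if (fs != 1000) stop("recording must be at 1000 Hz (resample first)")
  x <- rec@samples
  step <- round(fs / featureRate)
  if (length(x) < step) stop("recording shorter than one feature window")
  if (all(x == 0)) stop("degenerate all-zero recording")

  env <- abs(.analytic(x))
  homo <- exp(.lowpass(log(env + 1e-10), fs, 8, order = 1))
  bp <- .bandpass(x, fs, 20, 200)
  bandPow <- .lowpass(bp^2, fs, 8, order = 1)

  w <- pcgDWT(x, "db6", 4)
  wenv <- rep(abs(w$d[[4]]), each = 16)[seq_along(x)]
  wenv <- .lowpass(wenv, fs, 8, order = 1)

  f <- cbind(homomorphic = .blockMean(homo, step),
             hilbert = .blockMean(env, step),
             bandPower = .blockMean(bandPow, step),
             wavelet = .blockMean(wenv, step))
  scale(f)[, , drop = FALSE]
}

# per-feature-frame state labels from a ground-truth StateSequence
# (state at each block centre)
.frameLabels <- function(states, step, nFrames) {
  labels <- stateLabels(states)
  centres <- pmin((seq_len(nFrames) - 1) * step + ceiling(step / 2),
                  length(labels))
  factor(labels[centres], levels = .pcgStates)
}

#' Train the heart-sound segmenter on labelled recordings
#'
#' Fits a multinomial logistic emission model over envelope features and
#' estimates Gaussian duration parameters from the labelled run lengths.
#' Training is deterministic for fixed inputs.
#'
#' @param recordings list of [SimulatedPCG-class] (1000 Hz) with ground
#'   truth.
#' @param featureRate feature rate in Hz.
#' @return a [SegmenterModel-class].
#' @export
trainSegmenter <- function(recordings, featureRate = 50) {
  if (length(recordings) < 2) stop("need at least two labelled recordings")
  step <- round(1000 / featureRate)
  feats <- list(); labs <- list(); durRows <- list(); cycles <- numeric(0)
  for (r in recordings) {
    f <- extractEnvelopeFeatures(r, featureRate)
    feats[[length(feats) + 1]] <- f
    labs[[length(labs) + 1]] <- .frameLabels(r@trueStates, step, nrow(f))
    st <- r@trueStates
    durRows[[length(durRows) + 1]] <-
      data.frame(state = st@states, sec = st@lengths / st@samplingRate)
    if (length(r@trueS1Onsets) > 1)
      cycles <- c(cycles, diff(r@trueS1Onsets) / r@samplingRate)
  }
  X <- do.call(rbind, feats)
  y <- factor(unlist(lapply(labs, as.character)), levels = .pcgStates)
  if (nlevels(droplevels(y)) < 2) stop("labels contain a single class")
  df <- data.frame(state = y, X)
  fit <- nnet::multinom(state ~ homomorphic + hilbert + bandPower + wavelet,
                        data = df, trace = FALSE, maxit = 300)
  dur <- do.call(rbind, durRows)
  # drop censored first/last runs' distortion by trimming extremes
  dp <- do.call(rbind, lapply(split(dur$sec, dur$state), function(v)
    data.frame(meanSec = mean(v), sdSec = max(sd(v), 0.01))))
  dp <- data.frame(state = rownames(dp), dp, row.names = NULL)
  dp <- dp[match(.pcgStates, dp$state), ]
  new("SegmenterModel", emission = fit, durationParams = dp,
      featureRate = featureRate,
      meanCycleSec = if (length(cycles)) mean(cycles) else 0.857)
}

# discretised, truncated Gaussian duration pmf over 1..dmax feature frames
.durationPMF <- function(meanSec, sdSec, featureRate, dmax) {
  mu <- meanSec * featureRate
  sdf <- max(sdSec * featureRate, 0.5)
  d <- seq_len(dmax)
  p <- dnorm(d, mu, sdf)
  lo <- max(1, floor(mu - 3 * sdf)); hi <- ceiling(mu + 3 * sdf)
  p[d < lo | d > hi] <- 0
  if (sum(p) == 0) p[which.min(abs(d - mu))] <- 1
  p / sum(p)
}

#' Estimate heart rate from the homomorphic envelope
#'
#' Autocorrelation of the homomorphic envelope; the first prominent peak in
#' the physiological lag range (0.3-2 s) is taken as the cycle length.
#'
#' @param rec a [PCGRecording-class] at 1000 Hz.
#' @return estimated cycle length in seconds.
#' @export
estimateCycleLength <- function(rec) {
  fs <- rec@samplingRate
  env <- abs(.analytic(rec@samples))
  homo <- exp(.lowpass(log(env + 1e-10), fs, 8, order = 1))
  homo <- homo - mean(homo)
  maxLag <- min(round(2 * fs), length(homo) - 1)
  ac <- acf(homo, lag.max = maxLag, plot = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1
  win <- lags >= round(0.3 * fs)
  if (!any(win)) return(0.857)
  lags[win][which.max(ac[win])] / fs
}

#' Decode the four-state sequence of a recording
#'
#' Maximum a-posteriori state path under the cyclic state order with
#' Gaussian duration penalties (duration-constrained Viterbi at the feature
#' rate), upsampled back to sample resolution.
#'
#' @param rec a [PCGRecording-class] at 1000 Hz, at least 2 s long.
#' @param model a [SegmenterModel-class].
#' @return a [StateSequence-class] at the recording rate.
#' @export
segmentStates <- function(rec, model) {
  fs <- rec@samplingRate
  if (length(rec@samples) / fs < 2) stop("recording shorter than 2 s")
  fr <- model@featureRate
  step <- round(fs / fr)
  f <- extractEnvelopeFeatures(rec, fr)
  probs <- predict(model@emission, newdata = as.data.frame(f),
                   type = "probs")
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  logem <- log(pmax(probs[, .pcgStates, drop = FALSE], 1e-12))

  # adapt systole/diastole duration priors to this recording's heart rate
  # (autocorrelation of the homomorphic envelope); S1/S2 durations are
  # heart-rate independent
  dp <- model@durationParams
  est <- estimateCycleLength(rec)
  ratio <- est / model@meanCycleSec
  if (is.finite(ratio) && ratio > 0.4 && ratio < 2.5) {
    scale <- dp$state %in% c("systole", "diastole")
    dp$meanSec[scale] <- dp$meanSec[scale] * ratio
    dp$sdSec[scale] <- dp$sdSec[scale] * ratio
  }
  dp$sdSec <- pmax(dp$sdSec, 0.15 * dp$meanSec)
  dmax <- max(8, ceiling((max(dp$meanSec) + 4 * max(dp$sdSec)) * fr))
  dmax <- min(dmax, nrow(f))
  pmfs <- t(vapply(seq_len(4), function(k)
    .durationPMF(dp$meanSec[k], dp$sdSec[k], fr, dmax),
    numeric(dmax)))
  logdur <- log(pmax(pmfs, 1e-12))
  sf <- t(apply(pmfs, 1, function(p) rev(cumsum(rev(p)))))
  logsf <- log(pmax(sf, 1e-12))

  path <- cpp_hsmm_viterbi(logem, logdur, logsf)
  # upsample to sample resolution
  full <- rep(path, each = step)
  n <- length(rec@samples)
  if (length(full) < n) full <- c(full, rep(full[length(full)],
                                            n - length(full)))
  full <- full[seq_len(n)]
  full <- .refineS1Onsets(full, rec@samples, fs)
  r <- rle(full)
  StateSequence(.pcgStates[r$values], r$lengths, fs)
}

# Snap each decoded diastole->S1 boundary to the local rise of the
# homomorphic envelope (sub-frame refinement of the 20 ms Viterbi grid).
.refineS1Onsets <- function(full, samples, fs, windowSec = 0.04) {
  env <- exp(.lowpass(log(abs(.analytic(samples)) + 1e-10), fs, 8,
                      order = 1))
  n <- length(full)
  w <- round(windowSec * fs)
  onsets <- which(diff(full == 1L) == 1L) + 1L
  for (o in onsets) {
    lo <- max(1L, o - w); hi <- min(n, o + w)
    seg <- env[lo:hi]
    thr <- min(seg) + 0.25 * (max(seg) - min(seg))
    cross <- which(seg >= thr)
    if (length(cross) == 0) next
    oNew <- lo + cross[1] - 1L
    if (oNew < o) {                       # move the onset earlier
      # keep at least one diastole sample so the cyclic order survives
      if (oNew > 1L && full[oNew - 1L] == 4L &&
          all(full[oNew:(o - 1L)] == 4L))
        full[oNew:(o - 1L)] <- 1L
    } else if (oNew > o) {                # move the onset later
      if (oNew < n && full[oNew] == 1L &&
          all(full[o:(oNew - 1L)] == 1L))
        full[o:(oNew - 1L)] <- 4L
    }
  }
  full
}

#' Cut S1-onset-aligned analysis frames from a segmented recording
#'
#' Each frame starts at a detected S1 onset and spans `frameSeconds`
#' (1600 samples at 1000 Hz). After a frame ends, the next frame starts at
#' the first S1 onset at least `skipPeriods` estimated mean cycle lengths
#' later, so consecutive frames never overlap. Truncated tail frames are
#' discarded.
#'
#' @param rec a [PCGRecording-class] at 1000 Hz.
#' @param states a [StateSequence-class] for the recording (detected or
#'   ground truth).
#' @param frameSeconds frame length in seconds (default 1.6).
#' @param skipPeriods cardiac periods reserved between frames (default 2).
#' @return list of [PCGFrame-class]; empty (with a warning) if no S1 onset
#'   fits.
#' @export
extractFrames <- function(rec, states, frameSeconds = 1.6,
                          skipPeriods = 2) {
  fs <- rec@samplingRate
  flen <- round(frameSeconds * fs)
  onsets <- s1Onsets(states)
  n <- length(rec@samples)
  onsets <- onsets[onsets + flen - 1 <= n]
  if (length(onsets) == 0) {
    warning("no usable S1 onsets; returning empty frame list")
    return(list())
  }
  allOnsets <- s1Onsets(states)
  cycle <- if (length(allOnsets) > 1) mean(diff(allOnsets)) else fs
  frames <- list()
  nextStart <- onsets[1]
  i <- 1L
  while (TRUE) {
    cand <- onsets[onsets >= nextStart]
    if (length(cand) == 0) break
    st <- cand[1]
    frames[[i]] <- new("PCGFrame",
                       samples = rec@samples[st:(st + flen - 1)],
                       startIndex = as.integer(st),
                       subjectId = rec@subjectId,
                       classLabel = rec@classLabel)
    i <- i + 1L
    nextStart <- st + flen + round(skipPeriods * cycle)
  }
  frames
}

#' Per-sample segmentation accuracy against ground truth
#'
#' @param predicted,truth [StateSequence-class] objects of equal total
#'   length.
#' @return fraction of samples with matching state labels.
#' @export
segmentationAccuracy <- function(predicted, truth) {
  a <- stateLabels(predicted); b <- stateLabels(truth)
  if (length(a) != length(b)) stop("sequences differ in length")
  mean(a == b)
}
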