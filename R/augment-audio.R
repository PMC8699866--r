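# Audio-domain augmentation of 1.6 s frames: pitch shift (up/down), time
# stretch (slow/fast) via a phase vocoder, and silence trimming. Every
# technique re-fits its output to exactly 1600 samples.

#' Audio augmentation configuration
#'
#' @param pitchSemitones magnitude of the positive/negative pitch shifts.
#' @param stretchRates `c(slow, fast)` tempo factors (slow < 1 < fast).
#' @param trimThresholdDb silence threshold relative to the frame peak.
#' @return an `AudioAugmentConfig` list.
#' @export
audioAugmentConfig <- function(pitchSemitones = 2,
                               stretchRates = c(0.9, 1.1),
                               trimThresholdDb = -40) {
  if (any(stretchRates <= 0)) stop("stretch rates must be positive")
  if (!(stretchRates[1] < 1 && stretchRates[2] > 1))
    stop("need slow < 1 < fast")
  structure(list(pitchSemitones = pitchSemitones,
                 stretchRates = stretchRates,
                 trimThresholdDb = trimThresholdDb),
            class = "AudioAugmentConfig")
}

# Phase-vocoder time stretch: output duration = input duration / rate,
# pitch preserved. Hann analysis/synthesis, hop 64 of a 256 window.
.phaseVocoder <- function(x, rate, L = 256, hop = 64) {
  if (rate == 1) return(x)
  w <- .hanning(L)
  nCols <- floor((length(x) - L) / hop) + 1
  starts <- (seq_len(nCols) - 1) * hop
  S <- vapply(starts, function(s) fft(x[(s + 1):(s + L)] * w),
              complex(L))
  steps <- seq(1, nCols, by = rate)
  omega <- 2 * pi * (0:(L - 1)) / L * hop
  phase <- Arg(S[, 1])
  out <- numeric(ceiling(length(steps)) * hop + L)
  pos <- 1
  for (st in steps) {
    i <- floor(st)
    frac <- st - i
    mag <- if (i < nCols) (1 - frac) * Mod(S[, i]) + frac * Mod(S[, i + 1])
           else Mod(S[, nCols])
    spec <- mag * exp(1i * phase)
    grain <- Re(fft(spec, inverse = TRUE)) / L * w
    out[pos:(pos + L - 1)] <- out[pos:(pos + L - 1)] + grain
    # phase propagation with instantaneous-frequency correction
    if (i < nCols) {
      dphi <- Arg(S[, i + 1]) - Arg(S[, i]) - omega
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      phase <- phase + omega + dphi
    } else phase <- phase + omega
    pos <- pos + hop
  }
  # overlap-add gain of a Hann window at 4x overlap is 1.5
  out / 1.5
}

.refit <- function(x, n) {
  if (length(x) >= n) return(x[seq_len(n)])
  pad <- n - length(x)
  refl <- rev(x)[seq_len(min(pad, length(x)))]
  while (length(refl) < pad) refl <- c(refl, rev(refl))[seq_len(pad)]
  c(x, refl)
}

# resample by factor r (output length = length/r) via linear interpolation
# on the anti-aliased signal
.rateResample <- function(x, r, fs = 1000) {
  if (r > 1) {   # compression in time -> frequencies scale up; prefilter
    bf <- signal::butter(8, min(0.9 / r, 0.99))
    x <- signal::filtfilt(bf, x)
  }
  m <- max(2, round(length(x) / r))
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = m))$y
}

#' Apply one audio augmentation technique to a frame
#'
#' Pitch shifts scale the spectral content by `2^(semitones/12)` while
#' preserving duration (resample + phase-vocoder stretch); time stretches
#' change tempo while preserving pitch; `trim_silence` removes
#' leading/trailing samples below the threshold. Output is re-fitted to
#' exactly the input frame length (reflection pad or crop).
#'
#' @param frame a [PCGFrame-class].
#' @param technique one of `pitch_up`, `pitch_down`, `stretch_slow`,
#'   `stretch_fast`, `trim_silence`.
#' @param cfg an [audioAugmentConfig()].
#' @return a [PCGFrame-class] of identical length.
#' @export
augmentAudio <- function(frame, technique, cfg = audioAugmentConfig()) {
  x <- frame@samples
  n <- length(x)
  y <- switch(technique,
    pitch_up = {
      f <- 2^(cfg$pitchSemitones / 12)
      .phaseVocoder(.rateResample(x, f), 1 / f)
    },
    pitch_down = {
      f <- 2^(-cfg$pitchSemitones / 12)
      .phaseVocoder(.rateResample(x, f), 1 / f)
    },
    stretch_slow = .phaseVocoder(x, cfg$stretchRates[1]),
    stretch_fast = .phaseVocoder(x, cfg$stretchRates[2]),
    trim_silence = {
      thr <- max(abs(x)) * 10^(cfg$trimThresholdDb / 20)
      keep <- which(abs(x) > thr)
      if (length(keep) == 0) x else x[keep[1]:keep[length(keep)]]
    },
    stop("unknown augmentation technique: ", technique))
  new("PCGFrame", samples = .refit(y, n), startIndex = frame@startIndex,
      subjectId = frame@subjectId, classLabel = frame@classLabel)
}

.augTechniques <- c("pitch_up", "pitch_down", "stretch_slow",
                    "stretch_fast", "trim_silence")

#' Non-generative augmentation of a frame set
#'
#' Applies all five audio augmentation techniques to every frame and
#' converts the results to spectrograms: exactly 5 augmented images per
#' input frame, tagged `nongenerative_aug` (originals are not included).
#'
#' @param frames non-empty list of [PCGFrame-class].
#' @param cfg an [audioAugmentConfig()].
#' @param spectroCfg a [spectrogramConfig()].
#' @return a [SpectrogramSet-class] with `5 * length(frames)` images.
#' @export
augmentNonGenerativeDataset <- function(frames,
                                        cfg = audioAugmentConfig(),
                                        spectroCfg = spectrogramConfig()) {
  if (length(frames) == 0) stop("empty frame list")
  aug <- list()
  for (fr in frames)
    for (tech in .augTechniques)
      aug[[length(aug) + 1]] <- augmentAudio(fr, tech, cfg)
  set <- framesToSpectrograms(aug, spectroCfg, origin = "nongenerative_aug")
  info <- imageInfo(set)
  info$frameId <- paste0(info$frameId, "_",
                         rep(.augTechniques, length(frames)))
  set@info <- info
  set
}
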