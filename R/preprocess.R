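#' Resample a recording with anti-aliasing
#'
#' Zero-phase anti-alias filtering (8th-order Butterworth low-pass applied
#' forward and backward, cutoff at 90% of the target Nyquist) followed by
#' interpolation onto the target sample grid. Output length is
#' `round(N * target / source)`. The heart-sound band (20-200 Hz) passes
#' unchanged; content above the new Nyquist is attenuated far beyond 40 dB.
#'
#' @param rec a [PCGRecording-class].
#' @param targetRate target rate in Hz (default 1000).
#' @param allowUpsample permit target above source rate.
#' @return the resampled [PCGRecording-class].
#' @export
resampleRecording <- function(rec, targetRate = 1000,
                              allowUpsample = FALSE) {
  fs <- rec@samplingRate
  if (targetRate > fs && !allowUpsample)
    stop("upsampling requested (target ", targetRate, " > source ", fs,
         " Hz); set allowUpsample = TRUE to permit")
  x <- rec@samples
  n <- length(x)
  m <- round(n * targetRate / fs)
  if (targetRate < fs) {
    bf <- signal::butter(8, 0.9 * targetRate / fs)  # fraction of Nyquist
    x <- signal::filtfilt(bf, x)
  }
  tOld <- (seq_len(n) - 1) / fs
  tNew <- (seq_len(m) - 1) / targetRate
  y <- approx(tOld, x, xout = pmin(tNew, tOld[n]))$y
  .replaceSamples(rec, y, targetRate)
}

# Rebuild a recording around new samples, carrying simulator ground truth
# through (state runs and onsets are rescaled when the rate changes).
.replaceSamples <- function(rec, y, fs) {
  if (is(rec, "SimulatedPCG")) {
    ratio <- fs / rec@samplingRate
    st <- rec@trueStates
    if (ratio != 1) {
      ends <- round(cumsum(st@lengths) * ratio)
      ends[length(ends)] <- length(y)
      lens <- diff(c(0, ends))
      keep <- lens > 0
      st <- StateSequence(st@states[keep], lens[keep], fs)
      onsets <- as.integer(round((rec@trueS1Onsets - 1) * ratio) + 1)
      onsets <- onsets[onsets <= length(y)]
    } else {
      st <- StateSequence(st@states, st@lengths, fs)
      onsets <- rec@trueS1Onsets
    }
    new("SimulatedPCG", samples = y, samplingRate = fs,
        subjectId = rec@subjectId, classLabel = rec@classLabel,
        trueStates = st, trueS1Onsets = onsets)
  } else {
    new("PCGRecording", samples = y, samplingRate = fs,
        subjectId = rec@subjectId, classLabel = rec@classLabel)
  }
}

#' Wavelet denoising configuration
#'
#' @param wavelet wavelet name (`"db6"` default, `"db4"` available).
#' @param levels decomposition depth (default 5).
#' @param thresholdRule only `"universal"` (level-dependent) is provided.
#' @param thresholdMode `"soft"` (default) or `"hard"`.
#' @param spins number of circular shifts for translation-invariant
#'   (cycle-spinning) averaging; 1 disables it.
#' @return a `DenoiseConfig` list.
#' @export
denoiseConfig <- function(wavelet = "db6", levels = 5,
                          thresholdRule = "universal",
                          thresholdMode = "soft", spins = 8) {
  if (levels < 1) stop("levels must be >= 1")
  if (spins < 1) stop("spins must be >= 1")
  thresholdRule <- match.arg(thresholdRule, "universal")
  thresholdMode <- match.arg(thresholdMode, c("soft", "hard"))
  structure(list(wavelet = wavelet, levels = levels,
                 thresholdRule = thresholdRule,
                 thresholdMode = thresholdMode, spins = spins),
            class = "DenoiseConfig")
}

.shrink <- function(d, thr, mode) {
  if (mode == "soft") sign(d) * pmax(abs(d) - thr, 0)
  else d * (abs(d) > thr)
}

#' Wavelet-denoise a recording
#'
#' Translation-invariant wavelet shrinkage: the pyramid DWT is applied over
#' `spins` circular shifts and the unshifted reconstructions are averaged.
#' The noise scale is estimated once from the MAD of the finest detail
#' level (where heart-sound energy is negligible at 1000 Hz) and each level
#' `j` is thresholded at `sigma * sqrt(2 log n_j)` with soft shrinkage by
#' default. Output length equals input length; in-band tonal content is
#' preserved and broadband noise is attenuated.
#'
#' @param rec a [PCGRecording-class].
#' @param cfg a [denoiseConfig()].
#' @return the denoised [PCGRecording-class].
#' @export
denoiseRecording <- function(rec, cfg = denoiseConfig()) {
  x <- rec@samples
  n <- length(x)
  if (n <= 2^cfg$levels)
    stop("signal shorter than the wavelet decomposition support")
  if (all(x == 0)) return(rec)
  denOne <- function(xs) {
    w <- pcgDWT(xs, cfg$wavelet, cfg$levels)
    sigma <- mad(w$d[[1]], center = 0)
    if (sigma > 0) {
      for (j in seq_along(w$d)) {
        thr <- sigma * sqrt(2 * log(length(w$d[[j]])))
        w$d[[j]] <- .shrink(w$d[[j]], thr, cfg$thresholdMode)
      }
    }
    pcgIDWT(w)
  }
  acc <- numeric(n)
  for (s in seq_len(cfg$spins) - 1) {
    xs <- if (s == 0) x else c(x[(s + 1):n], x[1:s])
    ys <- denOne(xs)
    acc <- acc + (if (s == 0) ys else c(ys[(n - s + 1):n], ys[1:(n - s)]))
  }
  .replaceSamples(rec, acc / cfg$spins, rec@samplingRate)
}

#' Peak-normalise a recording
#'
#' Divides every sample by the maximum absolute amplitude, mapping the
#' signal into `[-1, 1]` with the sign pattern preserved. Idempotent and
#' scale-invariant.
#'
#' @param rec a [PCGRecording-class].
#' @return the normalised [PCGRecording-class].
#' @export
normalizeRecording <- function(rec) {
  m <- max(abs(rec@samples))
  if (m == 0) stop("degenerate all-zero signal cannot be normalised")
  .replaceSamples(rec, rec@samples / m, rec@samplingRate)
}

#' Full preprocessing chain
#'
#' Resample to `targetRate`, wavelet-denoise, peak-normalise.
#'
#' @param rec a [PCGRecording-class].
#' @param targetRate target rate in Hz.
#' @param cfg a [denoiseConfig()].
#' @return a preprocessed [PCGRecording-class].
#' @export
preprocessRecording <- function(rec, targetRate = 1000,
                                cfg = denoiseConfig()) {
  normalizeRecording(denoiseRecording(resampleRecording(rec, targetRate),
                                      cfg))
}
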