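#' Configuration for the synthetic PCG simulator
#'
#' Defaults mirror the study conditions the package emulates: 8000 Hz
#' acquisition, five-minute recordings, and a class-dependent S2 spectral
#' ceiling (about 150 Hz for the LVDD-like class, about 200 Hz for the
#' control-like class). Heart-sound bursts are Gaussian-enveloped
#' band-limited chirps; see the methods vignette for the waveform model.
#'
#' @param samplingRate sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param heartRateMean,heartRateSd between-subject heart-rate distribution
#'   (bpm).
#' @param s1Band S1 frequency band (Hz), `c(low, high)`.
#' @param s2Band S2 frequency band (Hz); if `NULL`, chosen from
#'   `classLabel`: `c(40, 150)` for lvdd, `c(40, 200)` for control.
#' @param s1S2AmplitudeRatio peak amplitude of S1 relative to S2.
#' @param systoleFraction fraction of the cycle from S1 onset to S2 onset.
#' @param noiseSnr additive white-noise level in dB SNR over the whole
#'   recording; `Inf` disables noise.
#' @param classLabel `"lvdd"` or `"control"`.
#' @param seed integer RNG seed.
#' @return a `PCGSimConfig` list.
#' @export
pcgSimConfig <- function(samplingRate = 8000, duration = 300,
                         heartRateMean = 70, heartRateSd = 7,
                         s1Band = c(20, 120), s2Band = NULL,
                         s1S2AmplitudeRatio = 1.5, systoleFraction = 0.35,
                         noiseSnr = 20, classLabel = "control",
                         seed = 1L) {
  if (!classLabel %in% .lvddClasses) stop("classLabel must be lvdd/control")
  if (is.null(s2Band))
    s2Band <- if (classLabel == "lvdd") c(40, 150) else c(40, 200)
  cfg <- list(samplingRate = samplingRate, duration = duration,
              heartRateMean = heartRateMean, heartRateSd = heartRateSd,
              s1Band = s1Band, s2Band = s2Band,
              s1S2AmplitudeRatio = s1S2AmplitudeRatio,
              systoleFraction = systoleFraction, noiseSnr = noiseSnr,
              classLabel = classLabel, seed = as.integer(seed))
  class(cfg) <- "PCGSimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$duration <= 0) stop("duration must be positive")
  if (cfg$samplingRate <= 0) stop("samplingRate must be positive")
  if (cfg$samplingRate <= 2 * cfg$s2Band[2])
    stop("samplingRate must exceed twice the S2 band ceiling")
  if (cfg$systoleFraction <= 0 || cfg$systoleFraction >= 1)
    stop("systoleFraction must lie in (0, 1)")
  invisible(cfg)
}

# Gaussian-enveloped linear chirp sweeping `band`, centred in a window of
# `n` samples. The envelope sd is duration/6 so the burst decays to ~1% at
# its edges.
.pcgBurst <- function(n, fs, band, amplitude) {
  t <- (seq_len(n) - (n + 1) / 2) / fs
  dur <- n / fs
  f0 <- band[1]; f1 <- band[2]
  # instantaneous frequency ramps f0 -> f1 across the burst
  tt <- t + dur / 2
  phase <- 2 * pi * (f0 * tt + (f1 - f0) / (2 * dur) * tt^2)
  amplitude * exp(-t^2 / (2 * (dur / 6)^2)) * sin(phase)
}

#' Simulate one phonocardiogram with ground-truth states
#'
#' Each cardiac cycle contains one S1 and one S2 burst (Gaussian-enveloped,
#' band-limited chirps) separated by the systolic fraction of a
#' jittered cycle length; white Gaussian noise is added at the configured
#' SNR. The returned object carries the exact per-sample state sequence and
#' true S1 onsets for scoring the segmenter.
#'
#' @param config a [pcgSimConfig()] list.
#' @param subjectId subject identifier.
#' @param heartRateBpm optional subject heart rate; defaults to
#'   `config$heartRateMean`.
#' @return a [SimulatedPCG-class].
#' @export
simulateRecording <- function(config, subjectId = "sim01",
                              heartRateBpm = NULL) {
  validateSimConfig(config)
  fs <- config$samplingRate
  N <- round(config$duration * fs)
  hr <- heartRateBpm %||% config$heartRateMean
  period <- 60 / hr

  withr_seed <- config$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)

  x <- numeric(N)
  states <- character(0)
  lengths <- integer(0)
  onsets <- integer(0)

  s1dur <- 0.10   # s, within the 70-140 ms convention
  s2dur <- 0.07   # s, within the 50-100 ms convention
  pos <- 1L
  while (pos <= N) {
    # per-cycle jitter: truncated normal around the subject period
    Tc <- 0
    while (Tc < 0.6 * period || Tc > 1.4 * period)
      Tc <- rnorm(1, period, 0.03 * period)
    nc <- round(Tc * fs)
    n1 <- max(1L, round(s1dur * fs))
    n2 <- max(1L, round(s2dur * fs))
    nsys <- round(config$systoleFraction * nc)
    # state runs within the cycle: S1, systole, S2, diastole
    runLen <- c(n1, max(1L, nsys - n1), n2,
                max(1L, nc - nsys - n2))
    # waveform: S1 burst inside the S1 run, S2 inside the S2 run
    s1 <- .pcgBurst(n1, fs, config$s1Band, config$s1S2AmplitudeRatio)
    s2 <- .pcgBurst(n2, fs, config$s2Band, 1)
    i1 <- pos
    i2 <- pos + runLen[1] + runLen[2]
    if (i1 + n1 - 1 <= N) {
      x[i1:(i1 + n1 - 1)] <- x[i1:(i1 + n1 - 1)] + s1
      # only bursts that fully fit count as ground-truth onsets
      onsets <- c(onsets, i1)
    }
    if (i2 + n2 - 1 <= N) x[i2:(i2 + n2 - 1)] <- x[i2:(i2 + n2 - 1)] + s2
    states <- c(states, .pcgStates)
    lengths <- c(lengths, runLen)
    pos <- pos + sum(runLen)
  }
  # truncate the run-length tiling to exactly N samples
  cum <- cumsum(lengths)
  keep <- which(cum - lengths < N)
  lengths <- lengths[keep]
  states <- states[keep]
  lengths[length(lengths)] <- N - (cum[keep[length(keep)]] -
                                     lengths[length(lengths)])
  onsets <- onsets[onsets <= N]

  if (is.finite(config$noiseSnr)) {
    psig <- mean(x^2)
    pnoise <- psig / 10^(config$noiseSnr / 10)
    x <- x + rnorm(N, 0, sqrt(pnoise))
  }
  if (old$had) assign(".Random.seed", old$seed, envir = globalenv())

  new("SimulatedPCG", samples = x, samplingRate = fs,
      subjectId = subjectId, classLabel = config$classLabel,
      trueStates = StateSequence(states, lengths, fs),
      trueS1Onsets = as.integer(onsets))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    list(had = TRUE, seed = get(".Random.seed", envir = globalenv()))
  else list(had = FALSE, seed = NULL)
}

#' Simulate a two-class PCG cohort
#'
#' One recording per subject; per-subject heart rates are drawn from the
#' configured between-subject distribution. Subject ids are unique and
#' prefixed by class.
#'
#' @param nLvdd,nControl subjects per class (the emulated cohort is 30 vs
#'   41).
#' @param baseConfig a [pcgSimConfig()]; its `classLabel`/`s2Band` are
#'   overridden per class.
#' @param seed integer seed controlling subject heart rates and per-subject
#'   simulation seeds.
#' @return list of [SimulatedPCG-class] objects.
#' @export
simulateCohort <- function(nLvdd = 30, nControl = 41,
                           baseConfig = pcgSimConfig(), seed = 1L) {
  if (nLvdd < 1 || nControl < 1) stop("need at least one subject per class")
  set.seed(seed)
  n <- nLvdd + nControl
  hrs <- pmin(pmax(rnorm(n, baseConfig$heartRateMean,
                         baseConfig$heartRateSd), 40), 180)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep("lvdd", nLvdd), rep("control", nControl))
  ids <- c(sprintf("lvdd%02d", seq_len(nLvdd)),
           sprintf("ctrl%02d", seq_len(nControl)))
  lapply(seq_len(n), function(i) {
    cfg <- baseConfig
    cfg$classLabel <- labels[i]
    cfg$s2Band <- if (labels[i] == "lvdd") c(40, 150) else c(40, 200)
    cfg$seed <- seeds[i]
    simulateRecording(cfg, subjectId = ids[i], heartRateBpm = hrs[i])
  })
}

#' Construct linearly separable synthetic spectrogram classes
#'
#' A desk-scale validation pattern: each class carries a bright horizontal
#' band in a class-specific row range (disjoint between classes) over a
#' noisy background, mimicking the band-limited energy signature that
#' separates spectrogram classes. Used to validate classifier and GAN
#' machinery where perfect class structure is known by construction.
#'
#' @param nPerClass images per class.
#' @param size image side length.
#' @param seed RNG seed.
#' @param nSubjectsPerClass synthetic subject ids to cycle through
#'   (for cross-validation plumbing).
#' @param noiseSd background noise level.
#' @return a [SpectrogramSet-class] with `2 * nPerClass` images.
#' @export
separableImageSet <- function(nPerClass, size = 32, seed = 1L,
                              nSubjectsPerClass = 5, noiseSd = 0.1) {
  set.seed(seed)
  n <- 2L * nPerClass
  px <- array(0, c(size, size, 3, n))
  bands <- list(lvdd = round(size * c(0.15, 0.30)),
                control = round(size * c(0.55, 0.70)))
  info <- data.frame(frameId = character(n), subjectId = character(n),
                     classLabel = rep(.lvddClasses, each = nPerClass),
                     origin = "real", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cl <- info$classLabel[i]
    g <- matrix(pmin(pmax(abs(rnorm(size * size, 0, noiseSd)), 0), 1),
                size, size)
    rows <- bands[[cl]][1]:bands[[cl]][2]
    g[rows, ] <- pmin(1, g[rows, ] + runif(length(rows) * size, 0.6, 0.9))
    for (ch in 1:3) px[, , ch, i] <- g
    j <- (i - 1L) %% nPerClass
    info$subjectId[i] <- sprintf("%s_s%02d", cl,
                                 j %% nSubjectsPerClass + 1L)
    info$frameId[i] <- sprintf("%s_img%04d", cl, i)
  }
  SpectrogramSet(px, info)
}

#' Write a simulated cohort to disk
#'
#' Writes one mono WAV per recording plus `manifest.csv`
#' (subject_id, path, label) and `boundaries.csv`
#' (subject_id, state, start_sample, end_sample; 1-based inclusive).
#'
#' @param recordings list of [SimulatedPCG-class].
#' @param dir output directory (created if missing).
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return the manifest data frame, invisibly.
#' @export
writeCohort <- function(recordings, dir, bits = 16) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recordings, function(r) {
    path <- file.path(dir, paste0(r@subjectId, ".wav"))
    writeWavePCG(r, path, bits = bits)
    data.frame(subject_id = r@subjectId, path = path,
               label = r@classLabel, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  bnd <- do.call(rbind, lapply(recordings, function(r) {
    st <- r@trueStates
    ends <- cumsum(st@lengths)
    starts <- ends - st@lengths + 1L
    data.frame(subject_id = r@subjectId, state = st@states,
               start_sample = starts, end_sample = ends,
               stringsAsFactors = FALSE)
  }))
  write.csv(bnd, file.path(dir, "boundaries.csv"), row.names = FALSE)
  invisible(manifest)
}
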