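# Shared fixtures, built once per test session.

.fixtures <- new.env()

# clean simulated recording at 1000 Hz with ground truth
cleanRec1k <- function(duration = 20, seed = 11, hr = 70) {
  key <- sprintf("rec_%s_%s_%s", duration, seed, hr)
  if (is.null(.fixtures[[key]])) {
    cfg <- pcgSimConfig(duration = duration, noiseSnr = Inf, seed = seed)
    r <- simulateRecording(cfg, heartRateBpm = hr)
    .fixtures[[key]] <- normalizeRecording(resampleRecording(r, 1000))
  }
  .fixtures[[key]]
}

# trained segmenter on a small clean cohort
fixtureSegmenter <- function() {
  if (is.null(.fixtures$segmenter)) {
    cfg <- pcgSimConfig(duration = 30, noiseSnr = Inf)
    recs <- simulateCohort(2, 2, cfg, seed = 77)
    prep <- lapply(recs, function(r)
      normalizeRecording(resampleRecording(r, 1000)))
    .fixtures$segmenter <- trainSegmenter(prep)
  }
  .fixtures$segmenter
}

# a 1600-sample sine frame
sineFrame <- function(freqHz = 100) {
  new("PCGFrame", samples = sin(2 * pi * freqHz * (0:1599) / 1000),
      startIndex = 1L, subjectId = "sub1", classLabel = "lvdd")
}

# brute-force windowed DFT (one-sided), the STFT oracle
naiveSTFT <- function(x, L = 256, hop = 10) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  nCols <- floor((length(x) - L) / hop) + 1
  E <- exp(-2i * pi * outer(0:(L - 1), 0:(L / 2)) / L)
  vapply(seq_len(nCols), function(t) {
    seg <- x[((t - 1) * hop + 1):((t - 1) * hop + L)] * w
    as.complex(crossprod(E, seg))
  }, complex(L / 2 + 1))
}

# brute-force duration-constrained Viterbi by enumeration of all run
# partitions (cyclic state order, censored first/last runs), mirroring the
# decoder's scoring exactly
bruteForceHSMM <- function(logem, logdur, logsf) {
  T <- nrow(logem); K <- ncol(logem); Dmax <- ncol(logdur)
  ce <- apply(logem, 2, cumsum)
  ce <- rbind(0, ce)
  best <- list(score = -Inf, path = NULL)
  # add a run of state k covering (t, t+d]; the first run (t == 0) and a
  # run reaching T are scored with the duration survival function
  recurse <- function(t, k, score, path) {
    for (d in seq_len(min(Dmax, T - t))) {
      t2 <- t + d
      em <- ce[t2 + 1, k] - ce[t + 1, k]
      if (t2 == T) {
        sc <- score + logsf[k, d] + em
        if (sc > best$score)
          best <<- list(score = sc, path = c(path, rep(k, d)))
      } else {
        sc <- score + (if (t == 0) logsf[k, d] else logdur[k, d]) + em
        recurse(t2, k %% K + 1, sc, c(path, rep(k, d)))
      }
    }
  }
  for (k0 in seq_len(K)) recurse(0, k0, -log(K), integer(0))
  best
}

# random small spectrogram set with given subjects
randomImageSet <- function(n, size = 32, seed = 1, label = "lvdd",
                           subject = "s1", origin = "real") {
  set.seed(seed)
  px <- array(runif(size * size * 3 * n), c(size, size, 3, n))
  SpectrogramSet(px, data.frame(
    frameId = sprintf("%s_%03d", subject, seq_len(n)),
    subjectId = subject, classLabel = label, origin = origin,
    stringsAsFactors = FALSE))
}
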