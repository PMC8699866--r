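test_that("envelope features have the contracted rate and alignment", {
  rec <- cleanRec1k(duration = 20, seed = 11)
  f <- extractEnvelopeFeatures(rec)
  expect_equal(nrow(f), floor(length(pcgSamples(rec)) / 20))
  expect_equal(ncol(f), 4)
  # columns are z-normalised
  expect_equal(unname(colMeans(f)), rep(0, 4), tolerance = 1e-8)
  expect_error(extractEnvelopeFeatures(
    PCGRecording(numeric(4000), 1000)), "degenerate")
  expect_error(extractEnvelopeFeatures(PCGRecording(rnorm(4000), 2000)),
               "1000 Hz")
  # envelope peaks align with true S1 centres within 20 ms
  env <- f[, "homomorphic"]
  st <- rec@trueStates
  ends <- cumsum(st@lengths); starts <- ends - st@lengths + 1L
  s1 <- which(st@states == "S1")
  s1 <- s1[-c(1, length(s1))]
  for (i in s1) {
    centreFrame <- (starts[i] + ends[i]) / 2 / 20
    lo <- max(1, floor(centreFrame - 5)); hi <- min(length(env),
                                                    ceiling(centreFrame + 5))
    # local max within +-100 ms window must be within +-20 ms (1 frame)
    peak <- lo - 1 + which.max(env[lo:hi])
    expect_lt(abs(peak - centreFrame) * 20 / 1000, 0.021)
  }
})

test_that("segmenter training estimates durations and is deterministic", {
  seg <- fixtureSegmenter()
  dp <- seg@durationParams
  expect_equal(dp$state, c("S1", "systole", "S2", "diastole"))
  expect_true(dp$meanSec[dp$state == "S1"] > 0.05 &&
              dp$meanSec[dp$state == "S1"] < 0.2)
  expect_true(all(dp$meanSec > 0))
  # held-out per-frame emission accuracy well above 4-class chance
  rec <- cleanRec1k(duration = 20, seed = 99)
  f <- extractEnvelopeFeatures(rec)
  labs <- asNamespace("pcgLVDD")$.frameLabels(rec@trueStates, 20, nrow(f))
  pred <- predict(seg@emission, newdata = as.data.frame(f))
  expect_gt(mean(as.character(pred) == as.character(labs)), 0.7)
  # determinism
  cfg <- pcgSimConfig(duration = 10, noiseSnr = Inf)
  recs <- lapply(simulateCohort(1, 1, cfg, seed = 5), function(r)
    normalizeRecording(resampleRecording(r, 1000)))
  m1 <- trainSegmenter(recs)
  m2 <- trainSegmenter(recs)
  expect_identical(coef(m1@emission), coef(m2@emission))
  expect_error(trainSegmenter(recs[1]), "at least two")
})

test_that("Viterbi decoding matches brute-force enumeration on toy inputs", {
  set.seed(42)
  nn <- asNamespace("pcgLVDD")
  for (rep in 1:4) {
    T <- 14; K <- 4; Dmax <- 5
    logem <- matrix(log(runif(T * K, 0.05, 1)), T, K)
    pmf <- t(vapply(1:K, function(k) {
      p <- runif(Dmax, 0.05, 1); p / sum(p)
    }, numeric(Dmax)))
    logdur <- log(pmf)
    logsf <- log(t(apply(pmf, 1, function(p) rev(cumsum(rev(p))))))
    fast <- nn$cpp_hsmm_viterbi(logem, logdur, logsf)
    slow <- bruteForceHSMM(logem, logdur, logsf)
    expect_equal(as.integer(fast), as.integer(slow$path))
  }
})

test_that("state decoding recovers the simulated ground truth", {
  seg <- fixtureSegmenter()
  rec <- cleanRec1k(duration = 20, seed = 31, hr = 60)
  st <- segmentStates(rec, seg)
  expect_true(validObject(st))
  expect_equal(sum(st@lengths), length(pcgSamples(rec)))
  expect_gt(segmentationAccuracy(st, rec@trueStates), 0.9)
  det <- s1Onsets(st)
  for (o in rec@trueS1Onsets)
    expect_lt(min(abs(det - o)) / 1000, 0.020)
  expect_error(segmentStates(PCGRecording(rnorm(1000), 1000), seg),
               "2 s")
})

test_that("segmentation accuracy degrades as noise increases", {
  seg <- fixtureSegmenter()
  accAt <- function(snr) {
    accs <- vapply(1:2, function(i) {
      cfg <- pcgSimConfig(duration = 15, noiseSnr = snr, seed = 300 + i)
      r <- normalizeRecording(resampleRecording(simulateRecording(cfg),
                                                1000))
      segmentationAccuracy(segmentStates(r, seg), r@trueStates)
    }, numeric(1))
    mean(accs)
  }
  a30 <- accAt(30); a0 <- accAt(0)
  expect_gt(a30, a0)
})

test_that("framing starts at S1 onsets, never overlaps and skips periods", {
  rec <- cleanRec1k(duration = 60, seed = 11, hr = 60)
  frames <- extractFrames(rec, rec@trueStates)
  expect_true(length(frames) > 0)
  expect_true(all(vapply(frames, function(f) length(f@samples), numeric(1))
                  == 1600))
  starts <- vapply(frames, function(f) f@startIndex, integer(1))
  expect_true(all(starts %in% rec@trueS1Onsets))
  expect_true(all(diff(starts) >= 1600))
  # 60 bpm: one frame every ~(1.6 s + 2 cycles) -> every 4th onset
  expect_equal(length(frames), 15, tolerance = 1)

  short <- PCGRecording(rnorm(1000), 1000)
  st <- StateSequence(c("S1", "systole", "S2", "diastole"),
                      c(100, 250, 80, 570), 1000)
  expect_warning(out <- extractFrames(short, st), "no usable S1")
  expect_length(out, 0)
})
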