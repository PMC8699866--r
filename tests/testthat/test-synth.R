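test_that("simulated recordings honour length, tiling and determinism", {
  cfg <- pcgSimConfig(duration = 5, noiseSnr = Inf, seed = 3)
  r <- simulateRecording(cfg)
  expect_equal(length(pcgSamples(r)), 5 * 8000)
  # states tile the recording exactly, in cyclic order
  expect_equal(sum(r@trueStates@lengths), length(pcgSamples(r)))
  expect_true(validObject(r@trueStates))
  expect_true(all(diff(r@trueS1Onsets) > 0))
  r2 <- simulateRecording(cfg)
  expect_identical(pcgSamples(r), pcgSamples(r2))

  expect_error(simulateRecording(pcgSimConfig(duration = 5, seed = 1,
                                              samplingRate = 200)),
               "samplingRate")
  expect_error(pcgSimConfig(duration = -1), "duration")
  expect_error(pcgSimConfig(systoleFraction = 1.2), "systoleFraction")
})

test_that("noise-free envelope peaks sit within 10 ms of burst centres", {
  cfg <- pcgSimConfig(duration = 8, noiseSnr = Inf, seed = 9)
  r <- simulateRecording(cfg)
  fs <- samplingRate(r)
  env <- abs(asNamespace("pcgLVDD")$.analytic(pcgSamples(r)))
  st <- r@trueStates
  ends <- cumsum(st@lengths)
  starts <- ends - st@lengths + 1L
  for (which in c("S1", "S2")) {
    idx <- which(st@states == which)
    idx <- idx[-length(idx)]
    for (i in idx) {
      centre <- (starts[i] + ends[i]) / 2
      peak <- starts[i] - 1 + which.max(env[starts[i]:ends[i]])
      expect_lt(abs(peak - centre) / fs, 0.010)
    }
  }
})

test_that("S2 spectral content separates the classes", {
  # Welch-style periodogram over ground-truth S2 segments: the 99th
  # percentile cutoff and the centroid are lower for the LVDD-like class
  s2spec <- function(classLabel, seed) {
    cfg <- pcgSimConfig(duration = 10, noiseSnr = Inf, seed = seed,
                        classLabel = classLabel)
    r <- simulateRecording(cfg)
    st <- r@trueStates
    ends <- cumsum(st@lengths); starts <- ends - st@lengths + 1L
    segs <- which(st@states == "S2")
    acc <- 0
    for (i in segs) {
      seg <- pcgSamples(r)[starts[i]:ends[i]]
      n <- 2^ceiling(log2(length(seg)))
      p <- Mod(fft(c(seg, numeric(n - length(seg)))))^2
      acc <- acc + p[1:(n / 2)] / length(segs)
    }
    freq <- (seq_len(n / 2) - 1) * samplingRate(r) / n
    cum <- cumsum(acc) / sum(acc)
    list(cut99 = freq[which(cum >= 0.99)[1]],
         centroid = sum(freq * acc) / sum(acc))
  }
  lv <- s2spec("lvdd", 5)
  ct <- s2spec("control", 5)
  expect_lt(lv$cut99, ct$cut99)
  expect_lt(lv$centroid, ct$centroid)
})

test_that("cohorts have the requested shape, unique ids and seeded HRs", {
  cfg <- pcgSimConfig(duration = 2, seed = 1)
  co <- simulateCohort(3, 4, cfg, seed = 10)
  expect_length(co, 7)
  labs <- vapply(co, groupLabel, character(1))
  expect_equal(sum(labs == "lvdd"), 3)
  ids <- vapply(co, subjectId, character(1))
  expect_false(anyDuplicated(ids) > 0)

  co2 <- simulateCohort(1, 1, cfg, seed = 10)
  expect_length(co2, 2)
  expect_false(co2[[1]]@subjectId == co2[[2]]@subjectId)

  coA <- simulateCohort(2, 2, cfg, seed = 1)
  coB <- simulateCohort(2, 2, cfg, seed = 2)
  hrA <- vapply(coA, function(r) length(r@trueS1Onsets), numeric(1))
  hrB <- vapply(coB, function(r) length(r@trueS1Onsets), numeric(1))
  expect_false(identical(pcgSamples(coA[[1]]), pcgSamples(coB[[1]])))
  expect_error(simulateCohort(0, 5, cfg, 1), "at least one")
})

test_that("class separation holds across many simulated subjects", {
  centroidOfS2 <- function(r) {
    st <- r@trueStates
    ends <- cumsum(st@lengths); starts <- ends - st@lengths + 1L
    segs <- which(st@states == "S2")
    num <- 0; den <- 0
    for (i in segs) {
      seg <- pcgSamples(r)[starts[i]:ends[i]]
      n <- 1024
      p <- (Mod(fft(c(seg, numeric(n - length(seg)))))^2)[1:(n / 2)]
      freq <- (seq_len(n / 2) - 1) * samplingRate(r) / n
      num <- num + sum(freq * p); den <- den + sum(p)
    }
    num / den
  }
  cfg <- pcgSimConfig(duration = 3, noiseSnr = 25)
  co <- simulateCohort(20, 20, cfg, seed = 4)
  cents <- vapply(co, centroidOfS2, numeric(1))
  labs <- vapply(co, groupLabel, character(1))
  expect_lt(mean(cents[labs == "lvdd"]), mean(cents[labs == "control"]))
})

test_that("cohort WAV/CSV round trip preserves samples and metadata", {
  dir <- withr::local_tempdir()
  cfg <- pcgSimConfig(duration = 1, seed = 2)
  co <- simulateCohort(1, 1, cfg, seed = 3)
  man <- writeCohort(co, dir, bits = 32)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "boundaries.csv")))
  back <- readWavePCG(man$path[1], subjectId = man$subject_id[1],
                      classLabel = man$label[1])
  expect_equal(samplingRate(back), 8000)
  expect_equal(pcgSamples(back), pcgSamples(co[[1]]), tolerance = 1e-6)
  bnd <- read.csv(file.path(dir, "boundaries.csv"))
  expect_equal(sum(bnd$end_sample - bnd$start_sample + 1),
               2 * length(pcgSamples(co[[1]])))
})
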