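test_that("stft columns equal the brute-force windowed DFT", {
  set.seed(8)
  x <- rnorm(1600)
  S <- stft(x)
  O <- naiveSTFT(x)
  expect_equal(dim(S), dim(O))
  expect_lt(max(Mod(S - O)), 1e-9)
  # 100 Hz sine at 1000 Hz with L = 256: argmax at bin 26
  Ss <- stft(sineFrame(100)@samples)
  expect_true(all(apply(Mod(Ss), 2, which.max) == 27))  # bin 26, 0-based
  # constant signal: energy confined to the window main lobe at DC
  # (a Hanning window spreads a constant over bins 0 and +-1)
  Sc <- stft(rep(2, 1600))
  expect_true(all(apply(Mod(Sc), 2, which.max) == 1))
  beyondLobe <- Mod(Sc[-(1:3), ])
  expect_lt(max(beyondLobe) / max(Mod(Sc[1, ])), 0.01)
  expect_error(stft(rnorm(100)), "shorter")
  expect_error(stft(rnorm(1600), spectrogramConfig(hop = 0)), "hop")
})

test_that("per-column windowed Parseval identity holds", {
  set.seed(9)
  x <- rnorm(1600)
  cfg <- spectrogramConfig()
  S <- stft(x, cfg)
  w <- attr(S, "window")
  L <- cfg$windowLength
  for (t in c(1, 50, 135)) {
    seg <- x[((t - 1) * cfg$hop + 1):((t - 1) * cfg$hop + L)] * w
    # reconstruct full two-sided energy from the one-sided spectrum
    full <- c(S[, t], Conj(S[(L / 2):2, t]))
    expect_equal(sum(Mod(full)^2) / L, sum(seg^2), tolerance = 1e-8)
  }
})

test_that("spectrogram images obey the 128x128x3 [0,1] contract", {
  img <- spectrogramImage(stft(sineFrame(100)@samples))
  expect_equal(dim(img), c(128, 128, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img[, , 1], img[, , 2])   # replicate3 default
  # an all-zero spectrum degenerates to a constant log image: zeros + warning
  S0 <- stft(numeric(1600))
  expect_warning(img0 <- spectrogramImage(S0), "constant")
  expect_true(all(img0 == 0))
  # colormap mode keeps shape and range
  cfg <- spectrogramConfig(channelMode = "colormap")
  img2 <- spectrogramImage(stft(sineFrame(50)@samples, cfg), cfg)
  expect_equal(dim(img2), c(128, 128, 3))
  expect_true(all(img2 >= 0 & img2 <= 1))
  expect_false(identical(img2[, , 1], img2[, , 2]))
})

test_that("a DC frame is brightest in the lowest-frequency row", {
  img <- spectrogramImage(stft(rep(1, 1600)))
  rowMean <- apply(img[, , 1], 1, mean)
  expect_equal(which.max(rowMean), 1)
  expect_gt(rowMean[1], 0.99)
})

test_that("frame sets convert to spectrogram sets with provenance", {
  frames <- list(sineFrame(60), sineFrame(110))
  set <- framesToSpectrograms(frames)
  expect_equal(nImages(set), 2)
  expect_equal(unique(imageInfo(set)$origin), "real")
  expect_equal(unique(imageInfo(set)$classLabel), "lvdd")
  expect_error(framesToSpectrograms(list()), "empty")
  # PNG export writes one file per image
  dir <- withr::local_tempdir()
  paths <- writeSpectrogramPNGs(set, dir)
  expect_true(all(file.exists(paths)))
  px <- png::readPNG(paths[1])
  expect_equal(dim(px)[1:2], c(128, 128))
})

test_that("simulated classes separate above 150 Hz in image space", {
  # control-class S2 energy extends beyond 150 Hz; LVDD-class stops near it
  mkImages <- function(cl, seed) {
    cfg <- pcgSimConfig(duration = 30, noiseSnr = 30, seed = seed,
                        classLabel = cl)
    r <- normalizeRecording(resampleRecording(simulateRecording(cfg), 1000))
    framesToSpectrograms(extractFrames(r, r@trueStates))
  }
  lv <- mkImages("lvdd", 71)
  ct <- mkImages("control", 72)
  # rows above 150 Hz: bin k covers k*1000/256 Hz -> rows > 39
  hi <- function(s) mean(s@pixels[40:128, , 1, ])
  expect_gt(hi(ct), hi(lv))
})
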