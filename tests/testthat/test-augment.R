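test_that("audio augmentations keep length and shift pitch as specified", {
  fr <- sineFrame(100)
  for (tech in c("pitch_up", "pitch_down", "stretch_slow", "stretch_fast",
                 "trim_silence")) {
    out <- augmentAudio(fr, tech)
    expect_length(out@samples, 1600)
  }
  # +12 semitones doubles the dominant frequency (periodogram argmax)
  domFreq <- function(x) {
    sp <- Mod(fft(x))[1:800]
    (which.max(sp) - 1) * 1000 / 1600
  }
  up <- augmentAudio(fr, "pitch_up", audioAugmentConfig(pitchSemitones = 12))
  expect_equal(domFreq(up@samples), 200, tolerance = 1000 / 1600 + 1e-9)
  dn <- augmentAudio(fr, "pitch_down",
                     audioAugmentConfig(pitchSemitones = 12))
  expect_equal(domFreq(dn@samples), 50, tolerance = 1000 / 1600 + 1e-9)
  # unit stretch rate is the identity up to resynthesis error
  pv <- asNamespace("pcgLVDD")$.phaseVocoder
  expect_identical(pv(fr@samples, 1), fr@samples)
  expect_error(augmentAudio(fr, "reverse"), "unknown")
})

test_that("non-generative augmentation yields 5 tagged images per frame", {
  frames <- list(sineFrame(80), sineFrame(120), sineFrame(60))
  set <- augmentNonGenerativeDataset(frames)
  expect_equal(nImages(set), 15)
  expect_true(all(imageInfo(set)$origin == "nongenerative_aug"))
  expect_true(all(imageInfo(set)$subjectId == "sub1"))
  expect_error(augmentNonGenerativeDataset(list()), "empty")
})

test_that("generator and discriminator shapes follow the reference stack", {
  nets <- buildDCGAN(ganConfig(imageSize = 128, seed = 2))
  nn <- asNamespace("pcgLVDD")
  z <- matrix(runif(100 * 2, -1, 1), 100, 2)
  x <- z
  shapes <- list()
  for (l in nets$generator@layers) {
    x <- nn$nnLayerForward(l, x, FALSE)$out
    shapes[[length(shapes) + 1]] <- dim(x)
  }
  # dense projection to (8,8,512), doublings to (128,128,3)
  expect_equal(shapes[[2]], c(8, 8, 512, 2))
  expect_equal(shapes[[5]], c(16, 16, 256, 2))
  expect_equal(shapes[[8]], c(32, 32, 128, 2))
  expect_equal(shapes[[11]], c(64, 64, 64, 2))
  expect_equal(shapes[[length(shapes)]], c(128, 128, 3, 2))
  expect_true(all(x >= -1 & x <= 1))       # Tanh output

  img <- array(runif(128 * 128 * 3 * 2), c(128, 128, 3, 2))
  y <- img * 2 - 1
  dshapes <- list()
  for (l in nets$discriminator@layers) {
    y <- nn$nnLayerForward(l, y, FALSE)$out
    dshapes[[length(dshapes) + 1]] <- if (is.null(dim(y))) length(y)
                                      else dim(y)
  }
  expect_equal(dshapes[[1]], c(64, 64, 64, 2))
  expect_equal(dshapes[[4]], c(32, 32, 128, 2))
  expect_equal(dshapes[[7]], c(16, 16, 256, 2))
  expect_equal(dshapes[[10]], c(8, 8, 512, 2))
  expect_equal(dshapes[[13]], c(4, 4, 1024, 2))
  p <- discriminatorProbability(nets$discriminator, img)
  expect_true(all(p > 0 & p < 1))

  # scaled test mode: 32x32 keeps 3 up-sampling stages worth of doubling
  nets32 <- buildDCGAN(ganConfig(imageSize = 32, seed = 2))
  g <- generateSamples(new("GANGenerator", layers = nets32$generator@layers,
                           config = nets32$generator@config), 3, seed = 1)
  expect_equal(dim(g@pixels), c(32, 32, 3, 3))
  expect_error(buildDCGAN(ganConfig(imageSize = 48)), "power of two")
})

test_that("adversarial losses match their closed forms", {
  l <- dcganLoss(rep(0.5, 8), rep(0.5, 8))
  expect_equal(l$lossD, 2 * log(2))
  expect_equal(l$lossG, log(2))
  lm <- dcganLoss(rep(0.5, 8), rep(0.5, 8), generatorLoss = "minimax")
  expect_equal(lm$lossG, -log(2))
  # perfect discriminator drives lossD to 0
  lp <- dcganLoss(rep(1 - 1e-9, 4), rep(1e-9, 4))
  expect_lt(lp$lossD, 1e-6)
  # non-saturating generator loss strictly decreasing in D(G(z))
  ds <- seq(0.05, 0.95, by = 0.1)
  lg <- vapply(ds, function(d) dcganLoss(0.5, d)$lossG, numeric(1))
  expect_true(all(diff(lg) < 0))
  expect_warning(dcganLoss(c(0, 0.5), c(0.5)), "clamped")
})

test_that("desk-scale DCGAN training is seeded, traced and reproducible", {
  real <- separableImageSet(24, size = 32, seed = 14)
  lv <- subsetImages(real, imageInfo(real)$classLabel == "lvdd")
  cfg <- ganConfig(imageSize = 32, epochs = 3, batchSize = 8, seed = 6)
  r1 <- trainDCGAN(lv, cfg)
  expect_equal(nrow(r1$trace), 3)
  r2 <- trainDCGAN(lv, cfg)
  expect_identical(r1$generator@layers[[1]]$W, r2$generator@layers[[1]]$W)
  expect_identical(r1$trace, r2$trace)
  expect_error(trainDCGAN(lv, ganConfig(imageSize = 32, batchSize = 64)),
               "batch")

  g1 <- generateSamples(r1$generator, 5, seed = 3, classLabel = "lvdd")
  g2 <- generateSamples(r1$generator, 5, seed = 3, classLabel = "lvdd")
  expect_identical(g1@pixels, g2@pixels)
  g3 <- generateSamples(r1$generator, 5, seed = 4, classLabel = "lvdd")
  expect_false(identical(g1@pixels, g3@pixels))
  expect_true(all(g1@pixels >= 0 & g1@pixels <= 1))
  expect_true(all(imageInfo(g1)$origin == "gan_generated"))
  expect_error(generateSamples(r1$generator, 0), "positive")
})

test_that("dataset expansion respects the coefficient bookkeeping", {
  real <- separableImageSet(6, size = 32, seed = 15)
  nets <- buildDCGAN(ganConfig(imageSize = 32, seed = 3))
  gens <- list(lvdd = nets$generator, control = nets$generator)
  ex <- expandDataset(real, gens, coefficient = 3, seed = 2)
  expect_equal(nImages(ex), 3 * nImages(real))
  info <- imageInfo(ex)
  expect_equal(sum(info$classLabel == "lvdd"), 18)
  expect_true(all(is.na(info$subjectId)))
  ex0 <- expandDataset(real, gens, coefficient = 0)
  expect_equal(nImages(ex0), 0)
  expect_error(expandDataset(real, gens, coefficient = -1),
               "non-negative")
})
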