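test_that("summary t-test matches a brute-force test on raw samples", {
  # construct raw samples with exactly the requested mean/sd/n
  makeRaw <- function(m, s, n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  for (i in 1:5) {
    set.seed(100 + i)
    mA <- runif(1, -5, 5); sA <- runif(1, 0.5, 3); nA <- sample(5:40, 1)
    mB <- runif(1, -5, 5); sB <- runif(1, 0.5, 3); nB <- sample(5:40, 1)
    a <- makeRaw(mA, sA, nA, i)
    b <- makeRaw(mB, sB, nB, 50 + i)
    ours <- summaryTTest(mA, sA, nA, mB, sB, nB)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    oursW <- summaryTTest(mA, sA, nA, mB, sB, nB, welch = TRUE)
    refW <- t.test(a, b)
    expect_equal(oursW$t, unname(refW$statistic), tolerance = 1e-9)
    expect_equal(oursW$df, unname(refW$parameter), tolerance = 1e-9)
  }
  ident <- summaryTTest(5, 1, 10, 5, 1, 10)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(summaryTTest(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("TSTR rejects single-class generated sets and is shuffle-stable", {
  real <- separableImageSet(10, size = 32, seed = 61)
  oneClass <- subsetImages(real, imageInfo(real)$classLabel == "lvdd")
  expect_error(similarityTSTR(oneClass, real), "both classes")
  # upper-bound sanity: training on a relabelled copy of the real set and
  # shuffle invariance under a fixed training seed
  gen <- real
  gen@info$origin <- "gan_generated"
  cfg <- cnnConfig(inputSize = 32, epochs = 6, batchSize = 16,
                   learningRate = 1e-3, seed = 4)
  a1 <- similarityTSTR(gen, real, cfg, repeats = 1, seed = 3)
  set.seed(10)
  perm <- sample(nImages(gen))
  a2 <- similarityTSTR(subsetImages(gen, perm), real, cfg, repeats = 1,
                       seed = 3)
  expect_gte(a1$accuracy, 0.9)   # same-set training accuracy bound
  expect_equal(a1$accuracy, a2$accuracy, tolerance = 0.1)
})

test_that("expansion sweep bookkeeping and the zero coefficient null", {
  real <- separableImageSet(12, size = 32, seed = 62,
                            nSubjectsPerClass = 3)
  plan <- makeCVPlan(real, k = 3, seed = 1)
  perfect <- function(fit, images) imageInfo(images)$classLabel
  stubGen <- function(cl, n, seed) {
    randomImageSet(n, size = 32, seed = seed + nchar(cl), label = cl,
                   subject = NA_character_, origin = "gan_generated")
  }
  sweep <- expansionSweep(real, stubGen, c(0, 1, 2),
                          cnnConfig(inputSize = 32), plan,
                          trainer = function(tr, va, cfg) NULL,
                          predictor = perfect)
  expect_equal(sweep$coefficient, c(0, 1, 2))
  expect_equal(sweep$nGenerated, c(0, 24, 48))
  # coefficient 0 equals plain CV on the real set
  plain <- runCrossValidation(real, NULL, cnnConfig(inputSize = 32), plan,
                              trainer = function(tr, va, cfg) NULL,
                              predictor = perfect)
  expect_equal(sweep$accMean[1],
               plain$summary$mean[plain$summary$metric == "accuracy"])
  expect_error(expansionSweep(real, stubGen, numeric(0),
                              cnnConfig(inputSize = 32), plan), "empty")
  expect_error(expansionSweep(real, stubGen, c(2, 1),
                              cnnConfig(inputSize = 32), plan),
               "ascending")
})

test_that("reports are complete, arithmetic-consistent and byte-stable", {
  dir <- withr::local_tempdir()
  sizes <- datasetSizes(3677, 4803)
  res <- list(datasetSizes = sizes,
              sweep = data.frame(coefficient = c(0, 4, 8),
                                 accMean = c(0.91, 0.95, 0.981)),
              tstrAccuracy = 0.869)
  p1 <- writeReport(res, dir, "r1")
  p2 <- writeReport(res, dir, "r2")
  expect_identical(readLines(p1["json"]), readLines(p2["json"]))
  parsed <- jsonlite::fromJSON(p1[["json"]])
  expect_equal(parsed$sweep$coefficient, c(0, 4, 8))
  # combined-set arithmetic
  expect_equal(sizes$lvdd[sizes$dataset == "RS+DCGAN"], 3677 + 29416)
  expect_equal(sizes$lvdd[sizes$dataset == "RS+DCGAN"], 33093)
  csv <- read.csv(p1[["csv"]])
  expect_true(all(c("table", "field", "value") %in% names(csv)))
})
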