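test_that("the CNN reproduces the reference layer dimensions", {
  shapes <- cnnLayerShapes(buildCNN(cnnConfig(seed = 1)))
  expect_equal(shapes[[1]], c(128, 128, 64, 1))   # Conv1
  expect_equal(shapes[[3]], c(64, 64, 64, 1))     # Maxpool1
  expect_equal(shapes[[4]], c(64, 64, 32, 1))     # Conv2
  expect_equal(shapes[[6]], c(32, 32, 32, 1))     # Maxpool2
  expect_equal(shapes[[7]], c(32, 32, 16, 1))     # Conv3
  expect_equal(shapes[[9]], c(16, 16, 16, 1))     # Maxpool3
  expect_equal(shapes[[11]], c(128, 1))           # FC1
  expect_equal(shapes[[12]], c(100, 1))           # FC2
  expect_equal(shapes[[length(shapes)]], c(2, 1)) # softmax logits
  expect_error(buildCNN(cnnConfig(inputSize = 100)), "power of two")
  expect_error(cnnConfig(dropout = 1), "dropout")
})

test_that("ReLU and max-pooling follow their definitions", {
  nn <- asNamespace("pcgLVDD")
  grid <- seq(-3, 3, by = 0.25)
  x <- array(grid, c(length(grid), 1, 1, 1))
  out <- nn$nnLayerForward(nn$nnAct("relu"), x, FALSE)$out
  expect_equal(as.numeric(out), ifelse(grid >= 0, grid, 0))
  xp <- array(c(1, 5, 2, 8,  3, 7, 4, 6, 0, -1, -2, -3, 9, 1, 1, 1),
              c(4, 4, 1, 1))
  mp <- nn$nnLayerForward(nn$nnPool(2, 2), xp, FALSE)$out
  expect_equal(as.numeric(mp), apply(expand.grid(i = c(1, 3), j = c(1, 3)),
               1, function(z) max(xp[z[1]:(z[1] + 1), z[2]:(z[2] + 1), 1, 1])))
})

test_that("softmax probabilities are normalised and permutation-stable", {
  set.seed(20)
  m <- buildCNN(cnnConfig(inputSize = 32, seed = 5))
  imgs <- randomImageSet(6, size = 32, seed = 3)
  p <- predictCNN(m, imgs)
  expect_equal(rowSums(p$probs), rep(1, 6), tolerance = 1e-6)
  perm <- c(4, 2, 6, 1, 3, 5)
  p2 <- predictCNN(m, subsetImages(imgs, perm))
  expect_equal(p2$probs, p$probs[perm, ])
  expect_equal(p2$labels, p$labels[perm])
  expect_error(predictCNN(m, randomImageSet(2, size = 16, seed = 1)),
               "shape")
})

test_that("training separates constructed classes and is traced", {
  full <- separableImageSet(40, size = 32, seed = 30)
  set.seed(1)
  idx <- sample(nImages(full))
  tr <- subsetImages(full, idx[1:60])
  va <- subsetImages(full, idx[61:80])
  cfg <- cnnConfig(inputSize = 32, epochs = 12, batchSize = 32,
                   learningRate = 1e-3, seed = 2)
  r <- trainCNN(tr, va, cfg, stopAtValAccuracy = 0.95)
  expect_lte(nrow(r$trace), 12)
  expect_gte(max(r$trace$valAcc, na.rm = TRUE), 0.95)
  # training loss decreases over the first epochs (no early exit)
  r5 <- trainCNN(tr, NULL, cnnConfig(inputSize = 32, epochs = 5,
                                     batchSize = 32, learningRate = 1e-3,
                                     seed = 2))
  expect_lt(r5$trace$loss[5], r5$trace$loss[1])
  # deterministic inference
  p1 <- predictCNN(r$model, va)
  p2 <- predictCNN(r$model, va)
  expect_identical(p1$probs, p2$probs)
  expect_gte(mean(p1$labels == imageInfo(va)$classLabel), 0.95)
  # single-class training set is rejected
  lvOnly <- subsetImages(full, imageInfo(full)$classLabel == "lvdd")
  expect_error(trainCNN(lvOnly, va, cfg), "both classes")
})

test_that("confusion metrics implement the exact rational formulas", {
  m <- confusionMetrics(confusionCounts(tp = 3, tn = 4, fp = 0, fn = 1))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.875)
  m2 <- confusionMetrics(confusionCounts(1, 1, 0, 0))
  expect_equal(unlist(m2), c(accuracy = 1, sensitivity = 1,
                             specificity = 1))
  expect_error(confusionMetrics(confusionCounts(0, 4, 1, 0)),
               "sensitivity undefined")
  expect_error(confusionCounts(-1, 2, 0, 0), "non-negative")
  # Acc lies between min(Se,Sp) and max(Se,Sp); equality at balance
  set.seed(3)
  for (i in 1:20) {
    cc <- confusionCounts(sample(1:20, 1), sample(1:20, 1),
                          sample(1:20, 1), sample(1:20, 1))
    mm <- confusionMetrics(cc)
    expect_gte(mm$accuracy, min(mm$sensitivity, mm$specificity) - 1e-12)
    expect_lte(mm$accuracy, max(mm$sensitivity, mm$specificity) + 1e-12)
  }
  mb <- confusionMetrics(confusionCounts(8, 6, 4, 2))  # equal class sizes
  expect_equal(mb$accuracy, (mb$sensitivity + mb$specificity) / 2)
})

test_that("CV plans are subject-wise with rotating fold roles", {
  imgs <- separableImageSet(30, size = 32, seed = 44,
                            nSubjectsPerClass = 5)
  plan <- makeCVPlan(imgs, k = 10, seed = 2)
  expect_equal(plan@k, 10L)
  expect_length(plan@folds, 10)
  expect_true(validateFoldAssignment(plan@folds, 10))
  # 10 subjects into 10 folds: exactly one subject per fold
  expect_equal(sort(unname(plan@folds)), 1:10)
  # every image is in the test role exactly once over the k repetitions
  foldOf <- plan@folds[imageInfo(imgs)$subjectId]
  seen <- integer(nImages(imgs))
  for (r in 1:10) seen <- seen + (foldOf == r)
  expect_true(all(seen == 1))
  expect_error(makeCVPlan(imgs, k = 11, seed = 1), "fewer subjects")
  # injected violation: one subject under two folds
  bad <- c(a = 1L, b = 2L, a = 2L)
  expect_error(validateFoldAssignment(bad, 2), "multiple folds")
})

test_that("cross-validation harness scores stubs and blocks leakage", {
  imgs <- separableImageSet(30, size = 32, seed = 45,
                            nSubjectsPerClass = 3)
  plan <- makeCVPlan(imgs, k = 3, seed = 9)
  perfect <- function(fit, images) imageInfo(images)$classLabel
  res <- runCrossValidation(imgs, NULL, cnnConfig(inputSize = 32), plan,
                            trainer = function(tr, va, cfg) NULL,
                            predictor = perfect)
  expect_equal(res$summary$mean[res$summary$metric == "accuracy"], 1)
  expect_equal(res$summary$sd[res$summary$metric == "accuracy"], 0)
  expect_equal(nrow(res$perFold), 3)

  # subject-tagged extra images follow their subject out of training:
  # the harness runs clean (its internal structural check passes) and the
  # extra images never coexist with their subject's test fold
  extra <- randomImageSet(4, size = 32, seed = 5, label = "lvdd",
                          subject = "lvdd_s01", origin = "nongenerative_aug")
  spyTrainer <- function(tr, va, cfg) {
    ti <- imageInfo(tr)
    aug <- ti[ti$origin == "nongenerative_aug", , drop = FALSE]
    expect_true(all(aug$subjectId %in% ti$subjectId[ti$origin == "real"]))
    NULL
  }
  res2 <- runCrossValidation(imgs, extra, cnnConfig(inputSize = 32),
                             plan, trainer = spyTrainer,
                             predictor = perfect)
  expect_equal(nrow(res2$perFold), 3)
  # direct leakage injection is detected
  expect_error(checkLeakage(data.frame(subjectId = c("a", "b")), "b"),
               "leakage")
})
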