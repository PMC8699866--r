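#' DCGAN configuration
#'
#' Adversarial training hyperparameters: Adam with learning rate 2e-4 and
#' momentum (beta1) 0.5, batch size 64, 300 epochs, Leaky ReLU slope 0.2,
#' latent dimension 100. `imageSize` is 128 for the full model and may be
#' scaled down (power of two, >= 32) for desk-scale work.
#'
#' @param latentDim latent vector length.
#' @param learningRate Adam learning rate.
#' @param adamBeta1 Adam first-moment decay.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param leakySlope Leaky ReLU negative slope.
#' @param imageSize image side length.
#' @param generatorLoss `"nonsaturating"` (cross-entropy, default) or
#'   `"minimax"`.
#' @param seed RNG seed.
#' @return a `GANConfig` list.
#' @export
ganConfig <- function(latentDim = 100, learningRate = 2e-4,
                      adamBeta1 = 0.5, batchSize = 64, epochs = 300,
                      leakySlope = 0.2, imageSize = 128,
                      generatorLoss = c("nonsaturating", "minimax"),
                      seed = 1L) {
  if (latentDim < 1) stop("latentDim must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(latentDim = latentDim, learningRate = learningRate,
                 adamBeta1 = adamBeta1, batchSize = batchSize,
                 epochs = epochs, leakySlope = leakySlope,
                 imageSize = imageSize,
                 generatorLoss = match.arg(generatorLoss),
                 seed = as.integer(seed)),
            class = "GANConfig")
}

# Channel-width rule shared by G and D: width(spatial) = (size/2)^2/spatial.
# At size 128 this reproduces the reference stack (512@8 ... 64@64 for G;
# 64@64 ... 1024@4 for D); smaller sizes drop leading up-sampling stages and
# keep the same halving pattern.
.ganWidth <- function(imageSize, spatial) as.integer((imageSize / 2)^2 / spatial)

#' Build the DCGAN generator and discriminator
#'
#' Generator: dense projection of the latent vector to an 8x8 volume
#' (batch-norm + ReLU), stride-2 5x5 transposed convolutions doubling the
#' size and halving the channels (batch-norm + ReLU), and a final stride-2
#' 5x5 transposed convolution to 3 channels with Tanh (no batch-norm).
#' Discriminator: mirrored stride-2 5x5 convolutions with batch-norm and
#' Leaky ReLU, then a dense sigmoid scalar (no batch-norm on the output).
#' At `imageSize = 128` the layer shapes match the reference architecture.
#'
#' @param cfg a [ganConfig()].
#' @return list with `generator` ([GANGenerator-class]) and
#'   `discriminator` ([GANDiscriminator-class]).
#' @export
buildDCGAN <- function(cfg = ganConfig()) {
  s <- cfg$imageSize
  if (s < 32 || bitwAnd(as.integer(s), as.integer(s) - 1L) != 0)
    stop("imageSize must be a power of two >= 32")
  set.seed(cfg$seed)
  nStages <- log2(s / 8)            # up-samplings after the 8x8 projection

  c8 <- .ganWidth(s, 8)
  gl <- list(nnDense(cfg$latentDim, 8 * 8 * c8, sd = 0.02),
             nnReshape(c(8, 8, c8)),
             nnBN(c8), nnAct("relu"))
  spatial <- 8
  cin <- c8
  for (i in seq_len(nStages - 1)) {
    spatial <- spatial * 2
    cout <- .ganWidth(s, spatial)
    gl <- c(gl, list(nnConvT(cin, cout), nnBN(cout), nnAct("relu")))
    cin <- cout
  }
  gl <- c(gl, list(nnConvT(cin, 3), nnAct("tanh")))

  dl <- list()
  spatial <- s
  cin <- 3
  while (spatial > 8) {
    spatial <- spatial / 2
    cout <- .ganWidth(s, spatial)
    dl <- c(dl, list(nnConv(cin, cout, k = 5, stride = 2, pad = 2,
                            sd = 0.02),
                     nnBN(cout), nnAct("lrelu", cfg$leakySlope)))
    cin <- cout
  }
  spatial <- spatial / 2
  cout <- .ganWidth(s, spatial)
  dl <- c(dl, list(nnConv(cin, cout, k = 5, stride = 2, pad = 2, sd = 0.02),
                   nnBN(cout), nnAct("lrelu", cfg$leakySlope),
                   nnFlatten(),
                   nnDense(spatial * spatial * cout, 1, sd = 0.02)))
  # final sigmoid applied in the loss for numerical stability

  list(generator = new("GANGenerator", layers = gl, config = unclass(cfg)),
       discriminator = new("GANDiscriminator", layers = dl,
                           config = unclass(cfg)))
}

#' Adversarial cross-entropy losses
#'
#' Discriminator loss `-[mean log D(x) + mean log(1 - D(G(z)))]`; generator
#' loss is the non-saturating form `-mean log D(G(z))` by default, or the
#' minimax form `mean log(1 - D(G(z)))`.
#'
#' @param dReal,dFake discriminator probabilities on real and generated
#'   batches (values in (0,1); exact 0/1 are clamped with a warning).
#' @param generatorLoss `"nonsaturating"` or `"minimax"`.
#' @return list with `lossD` and `lossG`.
#' @export
dcganLoss <- function(dReal, dFake,
                      generatorLoss = c("nonsaturating", "minimax")) {
  generatorLoss <- match.arg(generatorLoss)
  eps <- 1e-7
  if (any(dReal <= 0 | dReal >= 1) || any(dFake <= 0 | dFake >= 1))
    warning("probabilities at 0/1 clamped by epsilon")
  dReal <- pmin(pmax(dReal, eps), 1 - eps)
  dFake <- pmin(pmax(dFake, eps), 1 - eps)
  lossD <- -(mean(log(dReal)) + mean(log(1 - dFake)))
  lossG <- if (generatorLoss == "nonsaturating") -mean(log(dFake))
           else mean(log(1 - dFake))
  list(lossD = lossD, lossG = lossG)
}

.ganGenerate <- function(genLayers, z, train = FALSE) {
  nnForward(genLayers, z, train = train)
}

# element-wise sum of two nnBackward gradient lists
.addGrads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    for (p in names(a[[i]])) a[[i]][[p]] <- a[[i]][[p]] + b[[i]][[p]]
  }
  a
}

#' Train a DCGAN on one class of spectrograms
#'
#' Alternating generator/discriminator Adam updates on real images rescaled
#' to `[-1, 1]`; per-epoch mean losses are traced. Deterministic for a
#' fixed seed (single-threaded BLAS).
#'
#' @param real a [SpectrogramSet-class] with at least `batchSize` images
#'   (one class).
#' @param cfg a [ganConfig()].
#' @return list with `generator`, `discriminator` and `trace` (data.frame
#'   epoch/lossD/lossG).
#' @export
trainDCGAN <- function(real, cfg = ganConfig()) {
  n <- nImages(real)
  if (n < cfg$batchSize)
    stop("need at least one full batch of real images (", cfg$batchSize,
         ")")
  nets <- buildDCGAN(cfg)
  G <- nets$generator@layers
  D <- nets$discriminator@layers
  sG <- nnAdamInit(G)
  sD <- nnAdamInit(D)
  x <- real@pixels * 2 - 1
  set.seed(cfg$seed + 1L)
  tG <- 0; tD <- 0
  trace <- data.frame(epoch = integer(0), lossD = numeric(0),
                      lossG = numeric(0))
  bs <- cfg$batchSize
  eps <- 1e-7
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ld <- c(); lg <- c()
    for (start in seq(1, n - bs + 1, by = bs)) {
      idx <- ord[start:(start + bs - 1)]
      xr <- x[, , , idx, drop = FALSE]

      # (i) generator step: fix D, push gradients through D(G(z))
      z <- matrix(runif(cfg$latentDim * bs, -1, 1), cfg$latentDim, bs)
      fwG <- nnForward(G, z, train = TRUE)
      fwDg <- nnForward(D, fwG$out, train = TRUE)
      pg <- 1 / (1 + exp(-fwDg$out))
      pg <- pmin(pmax(pg, eps), 1 - eps)
      lg <- c(lg, if (cfg$generatorLoss == "nonsaturating")
        -mean(log(pg)) else mean(log(1 - pg)))
      # d/dlogit of the generator objective
      dlogit <- if (cfg$generatorLoss == "nonsaturating") (pg - 1) / bs
                else -pg / bs
      dim(dlogit) <- dim(fwDg$out)
      bwD <- nnBackward(D, fwDg$caches, dlogit, needGrads = FALSE)
      bwG <- nnBackward(G, fwG$caches, bwD$dx, needInputGrad = FALSE)
      tG <- tG + 1
      upd <- nnAdamStep(G, bwG$grads, sG, cfg$learningRate,
                        beta1 = cfg$adamBeta1, t = tG)
      G <- nnUpdateBNStats(upd$layers, fwG$caches)
      sG <- upd$state

      # (ii) discriminator step: fix G; real and fake batches go through
      # separate forward passes (separate batch-norm statistics), their
      # gradients are summed into one Adam update
      z2 <- matrix(runif(cfg$latentDim * bs, -1, 1), cfg$latentDim, bs)
      xf <- nnForward(G, z2, train = TRUE)$out
      fwR <- nnForward(D, xr, train = TRUE)
      pr <- pmin(pmax(1 / (1 + exp(-fwR$out)), eps), 1 - eps)
      dlogitR <- (pr - 1) / bs
      dim(dlogitR) <- dim(fwR$out)
      bwR <- nnBackward(D, fwR$caches, dlogitR, needInputGrad = FALSE)
      fwF <- nnForward(D, xf, train = TRUE)
      pf <- pmin(pmax(1 / (1 + exp(-fwF$out)), eps), 1 - eps)
      dlogitF <- pf / bs
      dim(dlogitF) <- dim(fwF$out)
      bwF <- nnBackward(D, fwF$caches, dlogitF, needInputGrad = FALSE)
      ld <- c(ld, -(mean(log(pr)) + mean(log(1 - pf))))
      tD <- tD + 1
      upd <- nnAdamStep(D, .addGrads(bwR$grads, bwF$grads), sD,
                        cfg$learningRate, beta1 = cfg$adamBeta1, t = tD)
      D <- nnUpdateBNStats(upd$layers, fwR$caches)
      sD <- upd$state
    }
    trace <- rbind(trace, data.frame(epoch = ep, lossD = mean(ld),
                                     lossG = mean(lg)))
  }
  list(generator = new("GANGenerator", layers = G, config = unclass(cfg)),
       discriminator = new("GANDiscriminator", layers = D,
                           config = unclass(cfg)),
       trace = trace)
}

#' Discriminator probability that images are real
#'
#' @param discriminator a [GANDiscriminator-class].
#' @param images (h,w,3,n) array in `[0, 1]` or a [SpectrogramSet-class].
#' @return numeric vector of probabilities strictly inside (0, 1).
#' @export
discriminatorProbability <- function(discriminator, images) {
  x <- if (is(images, "SpectrogramSet")) images@pixels else images
  out <- nnForward(discriminator@layers, x * 2 - 1, train = FALSE)$out
  p <- 1 / (1 + exp(-as.numeric(out)))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Sample images from a trained generator
#'
#' Tanh outputs in `[-1, 1]` are mapped to `[0, 1]`; images are tagged
#' `gan_generated` with no source subject (they are restricted to training
#' folds by the cross-validation harness).
#'
#' @param generator a [GANGenerator-class].
#' @param n number of images.
#' @param seed RNG seed for the latent draws.
#' @param classLabel class label to attach.
#' @return a [SpectrogramSet-class].
#' @export
generateSamples <- function(generator, n, seed = 1L,
                            classLabel = NA_character_) {
  if (n <= 0) stop("n must be positive")
  cfg <- generator@config
  set.seed(seed)
  z <- matrix(runif(cfg$latentDim * n, -1, 1), cfg$latentDim, n)
  s <- cfg$imageSize
  px <- array(0, c(s, s, 3, n))
  bs <- 64
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    out <- nnForward(generator@layers, z[, idx, drop = FALSE],
                     train = FALSE)$out
    px[, , , idx] <- pmin(pmax((out + 1) / 2, 0), 1)
  }
  info <- data.frame(frameId = sprintf("gen_%s_%d_%04d", classLabel, seed,
                                       seq_len(n)),
                     subjectId = NA_character_,
                     classLabel = classLabel, origin = "gan_generated",
                     stringsAsFactors = FALSE)
  SpectrogramSet(px, info)
}

#' Expand a real dataset with generated images
#'
#' Produces `coefficient` generated images per real image, per class, using
#' the per-class generators.
#'
#' @param real a [SpectrogramSet-class] of real images (both classes or
#'   one).
#' @param generators named list of [GANGenerator-class] objects
#'   (`lvdd`, `control`).
#' @param coefficient expansion coefficient (>= 0).
#' @param seed base seed for sampling.
#' @return a [SpectrogramSet-class] of generated images (empty set with 0
#'   images if `coefficient` is 0).
#' @export
expandDataset <- function(real, generators, coefficient, seed = 1L) {
  if (coefficient < 0) stop("coefficient must be non-negative")
  info <- imageInfo(real)
  d <- dim(real@pixels)
  if (coefficient == 0) {
    return(SpectrogramSet(array(0, c(d[1], d[2], 3, 0)),
                          info[0, , drop = FALSE]))
  }
  sets <- list()
  for (cl in intersect(.lvddClasses, unique(info$classLabel))) {
    nReal <- sum(info$classLabel == cl)
    g <- generators[[cl]]
    if (is.null(g)) stop("no generator for class ", cl)
    sets[[cl]] <- generateSamples(g, coefficient * nReal,
                                  seed = seed + match(cl, .lvddClasses),
                                  classLabel = cl)
  }
  do.call(bindSpectrogramSets, unname(sets))
}
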