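#' CNN configuration
#'
#' The compact spectrogram classifier: three 3x3 stride-1 convolutions with
#' 64/32/16 channels, each followed by ReLU and 2x2 stride-2 max-pooling,
#' then fully connected layers of 128 and 100 units (dropout 0.5 after the
#' second) and a 2-class softmax. Adam with learning rate 1e-4.
#'
#' @param inputSize image side length (128 for the full model; smaller
#'   powers of two for desk-scale work).
#' @param learningRate Adam learning rate.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param dropout dropout probability after the second fully connected
#'   layer.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return a `CNNConfig` list.
#' @export
cnnConfig <- function(inputSize = 128, learningRate = 1e-4, epochs = 500,
                      batchSize = 64, dropout = 0.5, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(inputSize = inputSize, learningRate = learningRate,
                 epochs = epochs, batchSize = batchSize, dropout = dropout,
                 seed = as.integer(seed)),
            class = "CNNConfig")
}

#' Build the spectrogram CNN
#'
#' Layer shapes at `inputSize = 128` follow the reference architecture:
#' (128,128,3) -> (128,128,64) -> (64,64,64) -> (64,64,32) -> (32,32,32)
#' -> (32,32,16) -> (16,16,16) -> 128 -> 100 -> 2 (softmax).
#'
#' @param cfg a [cnnConfig()].
#' @return a [CNNModel-class] (untrained).
#' @export
buildCNN <- function(cfg = cnnConfig()) {
  s <- cfg$inputSize
  if (s < 8 || bitwAnd(s, s - 1L) != 0)
    stop("inputSize must be a power of two >= 8")
  set.seed(cfg$seed)
  flat <- (s / 8)^2 * 16
  layers <- list(
    nnConv(3, 64, k = 3, stride = 1, pad = 1, sd = sqrt(2 / (9 * 3))),
    nnAct("relu"),
    nnPool(2, 2),
    nnConv(64, 32, k = 3, stride = 1, pad = 1, sd = sqrt(2 / (9 * 64))),
    nnAct("relu"),
    nnPool(2, 2),
    nnConv(32, 16, k = 3, stride = 1, pad = 1, sd = sqrt(2 / (9 * 32))),
    nnAct("relu"),
    nnPool(2, 2),
    nnFlatten(),
    nnDense(flat, 128),
    nnDense(128, 100),
    nnDropout(cfg$dropout),
    nnDense(100, 2))
  new("CNNModel", layers = layers, config = unclass(cfg))
}

#' Number of trainable parameters of the CNN
#'
#' @param model a [CNNModel-class] (default: the full 128x128 model).
#' @return integer parameter count.
#' @export
cnnParameterCount <- function(model = buildCNN()) {
  nnCountParams(model@layers)
}

# images of a SpectrogramSet as a (h,w,3,n) batch array, labels as 1/2
# (1 = lvdd, the positive class)
.setToBatch <- function(set) {
  y <- match(imageInfo(set)$classLabel, .lvddClasses)
  list(x = set@pixels, y = y)
}

.cnnForwardLogits <- function(model, x, train = FALSE) {
  nnForward(model@layers, x, train = train)
}

#' Train the CNN
#'
#' Minimises cross-entropy with Adam. Dropout is active only during
#' training; per-epoch training loss/accuracy and validation accuracy are
#' recorded.
#'
#' @param train,val [SpectrogramSet-class] training and validation sets
#'   (both classes must be present in `train`).
#' @param cfg a [cnnConfig()].
#' @param stopAtValAccuracy optional early-exit threshold on validation
#'   accuracy.
#' @return list with elements `model` ([CNNModel-class]) and `trace`
#'   (data.frame epoch/loss/trainAcc/valAcc).
#' @export
trainCNN <- function(train, val = NULL, cfg = cnnConfig(),
                     stopAtValAccuracy = NULL) {
  tb <- .setToBatch(train)
  if (length(unique(tb$y)) < 2)
    stop("training set must contain both classes")
  model <- buildCNN(cfg)
  layers <- model@layers
  state <- nnAdamInit(layers)
  n <- length(tb$y)
  bs <- min(cfg$batchSize, n)
  set.seed(cfg$seed + 1L)
  step <- 0
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      trainAcc = numeric(0), valAcc = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c(); hits <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      xb <- tb$x[, , , idx, drop = FALSE]
      yb <- tb$y[idx]
      fw <- nnForward(layers, xb, train = TRUE)
      probs <- .softmax(fw$out)
      eps <- 1e-12
      losses <- c(losses, -mean(log(probs[cbind(yb, seq_along(yb))] + eps)))
      hits <- hits + sum(apply(probs, 2, which.max) == yb)
      onehot <- matrix(0, 2, length(yb))
      onehot[cbind(yb, seq_along(yb))] <- 1
      dlogits <- (probs - onehot) / length(yb)
      bw <- nnBackward(layers, fw$caches, dlogits, needInputGrad = FALSE)
      step <- step + 1
      upd <- nnAdamStep(layers, bw$grads, state, cfg$learningRate,
                        beta1 = 0.9, t = step)
      layers <- upd$layers
      state <- upd$state
    }
    model@layers <- layers
    valAcc <- NA_real_
    if (!is.null(val) && nImages(val) > 0) {
      pv <- predictCNN(model, val)
      valAcc <- mean(pv$labels == imageInfo(val)$classLabel)
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses),
                                     trainAcc = hits / n, valAcc = valAcc))
    if (!is.null(stopAtValAccuracy) && !is.na(valAcc) &&
        valAcc >= stopAtValAccuracy) break
  }
  model@layers <- layers
  list(model = model, trace = trace)
}

#' Predict class probabilities and labels
#'
#' Softmax probabilities with argmax labelling; a tie at probability 0.5 is
#' broken toward the control class. Inference is deterministic (dropout
#' disabled).
#'
#' @param model a trained [CNNModel-class].
#' @param images a [SpectrogramSet-class] or (h,w,3,n) array.
#' @return list with `probs` (n x 2 matrix, columns lvdd/control) and
#'   `labels` (character).
#' @export
predictCNN <- function(model, images) {
  x <- if (is(images, "SpectrogramSet")) images@pixels else images
  if (length(dim(x)) != 4 || dim(x)[1] != model@config$inputSize)
    stop("image shape does not match the model input size")
  n <- dim(x)[4]
  bs <- 64
  probs <- matrix(0, n, 2, dimnames = list(NULL, .lvddClasses))
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    fw <- nnForward(model@layers, x[, , , idx, drop = FALSE], train = FALSE)
    probs[idx, ] <- t(.softmax(fw$out))
  }
  labels <- ifelse(probs[, "lvdd"] > 0.5, "lvdd", "control")
  list(probs = probs, labels = labels)
}

#' Per-layer output shapes of the CNN
#'
#' @param model a [CNNModel-class].
#' @return list of integer shape vectors, one per layer, from a forward
#'   pass on a single zero image.
#' @export
cnnLayerShapes <- function(model = buildCNN()) {
  s <- model@config$inputSize
  x <- array(0, c(s, s, 3, 1))
  shapes <- list()
  for (i in seq_along(model@layers)) {
    r <- nnLayerForward(model@layers[[i]], x, train = FALSE)
    x <- r$out
    shapes[[i]] <- if (is.null(dim(x))) length(x) else dim(x)
  }
  shapes
}
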