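# Internal neural-network engine: layer forward/backward passes over the
# C++ convolution/pooling primitives, spatial batch normalisation, Adam.
# Activations are (H, W, C, N) arrays or (features, N) matrices.

nnConv <- function(cin, cout, k = 3, stride = 1, pad = 1, sd = 0.02) {
  list(type = "conv",
       W = array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = numeric(cout), stride = stride, pad = pad)
}

# transposed conv: input (H,W,cin) -> (2H,2W,cout) for k=5,s=2,p=2,op=1;
# weights are (k, k, cout, cin), the layout of the adjoint convolution
nnConvT <- function(cin, cout, k = 5, stride = 2, pad = 2, outPad = 1,
                    sd = 0.02) {
  list(type = "convt",
       W = array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cout, cin)),
       b = numeric(cout), stride = stride, pad = pad, outPad = outPad)
}

nnDense <- function(nin, nout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / nin)
  list(type = "dense", W = matrix(rnorm(nin * nout, 0, sd), nout, nin),
       b = numeric(nout))
}

nnPool <- function(size = 2, stride = 2)
  list(type = "pool", size = size, stride = stride)
nnFlatten <- function() list(type = "flatten")
nnReshape <- function(dim) list(type = "reshape", dim = dim)
nnBN <- function(channels, momentum = 0.9)
  list(type = "bn", gamma = rep(1, channels), beta = numeric(channels),
       runMean = numeric(channels), runVar = rep(1, channels),
       momentum = momentum)
nnAct <- function(fun, slope = 0.2)
  list(type = "act", fun = fun, slope = slope)
nnDropout <- function(p) list(type = "dropout", p = p)

nnLayerForward <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      out <- cpp_conv_fwd(x, layer$W, layer$b, layer$stride, layer$pad)
      list(out = out, cache = list(x = x))
    },
    convt = {
      out <- cpp_convt_fwd(x, layer$W, layer$b, layer$stride, layer$pad,
                           layer$outPad)
      list(out = out, cache = list(x = x))
    },
    dense = {
      out <- layer$W %*% x + layer$b
      list(out = out, cache = list(x = x))
    },
    pool = {
      r <- cpp_maxpool_fwd(x, layer$size, layer$stride)
      list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    flatten = {
      d <- dim(x)
      y <- x; dim(y) <- c(prod(d[1:3]), d[4])
      list(out = y, cache = list(xdim = d))
    },
    reshape = {
      n <- ncol(x)
      y <- x; dim(y) <- c(layer$dim, n)
      list(out = y, cache = list(n = n))
    },
    bn = {
      r <- cpp_bn_fwd(x, as.numeric(layer$gamma), as.numeric(layer$beta),
                      as.numeric(layer$runMean), as.numeric(layer$runVar),
                      train)
      list(out = r$out,
           cache = list(xhat = r$xhat, inv = r$inv, m = r$m, v = r$v,
                        train = train))
    },
    act = {
      out <- switch(layer$fun,
        relu = pmax(x, 0),
        lrelu = pmax(x, 0) + layer$slope * pmin(x, 0),
        tanh = tanh(x),
        sigmoid = 1 / (1 + exp(-x)))
      if (!is.null(dim(x))) dim(out) <- dim(x)
      list(out = out, cache = list(x = x, out = out))
    },
    dropout = {
      if (train && layer$p > 0) {
        mask <- (runif(length(x)) >= layer$p) / (1 - layer$p)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask))
      } else list(out = x, cache = list(mask = NULL))
    },
    stop("unknown layer type"))
}

nnLayerBackward <- function(layer, cache, dout, wantDx = TRUE,
                            wantGrads = TRUE) {
  switch(layer$type,
    conv = {
      g <- cpp_conv_bwd(cache$x, layer$W, dout, layer$stride, layer$pad,
                        wantDx, wantGrads)
      list(dx = if (wantDx) g$dx else NULL,
           grads = if (wantGrads) list(W = g$dw, b = g$db))
    },
    convt = {
      g <- cpp_convt_bwd(cache$x, layer$W, dout, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(W = g$dw, b = g$db))
    },
    dense = {
      list(dx = crossprod(layer$W, dout),
           grads = list(W = tcrossprod(dout, cache$x),
                        b = rowSums(dout)))
    },
    pool = {
      list(dx = cpp_maxpool_bwd(dout, cache$argmax, cache$xdim),
           grads = NULL)
    },
    flatten = {
      dx <- dout; dim(dx) <- cache$xdim
      list(dx = dx, grads = NULL)
    },
    reshape = {
      dx <- dout; dim(dx) <- c(prod(dim(dout)[1:3]), cache$n)
      list(dx = dx, grads = NULL)
    },
    bn = {
      r <- cpp_bn_bwd(dout, cache$xhat, as.numeric(cache$inv),
                      as.numeric(layer$gamma))
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    act = {
      dx <- switch(layer$fun,
        relu = dout * (cache$x > 0),
        lrelu = dout * ((cache$x > 0) + layer$slope * (cache$x <= 0)),
        tanh = dout * (1 - cache$out^2),
        sigmoid = dout * cache$out * (1 - cache$out))
      if (!is.null(dim(dout))) dim(dx) <- dim(dout)
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    })
}

nnForward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nnLayerForward(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

# needInputGrad: propagate dx through the first layer (FALSE saves work
# when the network input is data); needGrads: collect parameter gradients
# (FALSE when only dx is needed, e.g. the discriminator inside a
# generator update).
nnBackward <- function(layers, caches, dout, needInputGrad = TRUE,
                       needGrads = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nnLayerBackward(layers[[i]], caches[[i]], dout,
                         wantDx = (i > 1 || needInputGrad),
                         wantGrads = needGrads)
    dout <- r$dx
    if (!is.null(r$grads)) grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# update batch-norm running statistics from the caches of a training pass
nnUpdateBNStats <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && isTRUE(caches[[i]]$train)) {
      mom <- layers[[i]]$momentum
      layers[[i]]$runMean <- mom * layers[[i]]$runMean +
        (1 - mom) * caches[[i]]$m
      layers[[i]]$runVar <- mom * layers[[i]]$runVar +
        (1 - mom) * caches[[i]]$v
    }
  }
  layers
}

.paramNames <- c("W", "b", "gamma", "beta")

nnAdamInit <- function(layers) {
  lapply(layers, function(l) {
    ps <- intersect(names(l), .paramNames)
    if (length(ps) == 0) return(NULL)
    setNames(lapply(ps, function(p)
      list(m = array(0, dim(as.array(l[[p]])) %||% length(l[[p]])),
           v = array(0, dim(as.array(l[[p]])) %||% length(l[[p]])))), ps)
  })
}

nnAdamStep <- function(layers, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, t = 1) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]])) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      d <- dim(layers[[i]][[p]])
      if (is.null(d)) upd <- as.numeric(upd) else dim(upd) <- d
      layers[[i]][[p]] <- layers[[i]][[p]] - upd
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

nnCountParams <- function(layers) {
  sum(vapply(layers, function(l) {
    ps <- intersect(names(l), .paramNames)
    sum(vapply(ps, function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

.softmax <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
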