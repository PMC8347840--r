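# Internal minibatch conv-net engine. Activations are 4-D arrays
# [H, W, C, N]; layers are plain lists; conv/pool inner loops live in src/.
# Everything is deterministic given the R RNG state.

initConv <- function(kh, kw, cin, cout) {
  list(w = array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = rep(0, cout))
}

convLayer <- function(kh, kw, cin, cout, relu = TRUE, stride = 1,
                      pad = (kh - 1) %/% 2) {
  c(list(type = "conv", relu = relu, stride = stride, pad = pad),
    initConv(kh, kw, cin, cout))
}

poolLayer <- function(k = 2, stride = 2, pad = 0)
  list(type = "pool", k = k, stride = stride, pad = pad)

# 2x2 stride-2 average pooling: keeps pooled means equal to region means,
# so global average pooling downstream still measures area fractions
# (max pooling would erase small dark structures such as lesions).
avgPoolLayer <- function() list(type = "avgpool")

avgPoolFw <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  ri <- seq_len(2L * h2); ci <- seq_len(2L * w2)
  x <- x[ri, ci, , , drop = FALSE]
  odd <- seq(1L, 2L * h2, by = 2L)
  xr <- x[odd, , , , drop = FALSE] + x[odd + 1L, , , , drop = FALSE]
  oddc <- seq(1L, 2L * w2, by = 2L)
  (xr[, oddc, , , drop = FALSE] + xr[, oddc + 1L, , , drop = FALSE]) / 4
}

avgPoolBw <- function(dy, xdim) {
  d <- dim(dy)
  dx <- array(0, dim = xdim)
  g <- dy / 4
  odd <- seq(1L, 2L * d[1], by = 2L); oddc <- seq(1L, 2L * d[2], by = 2L)
  dx[odd, oddc, , ] <- g
  dx[odd + 1L, oddc, , ] <- g
  dx[odd, oddc + 1L, , ] <- g
  dx[odd + 1L, oddc + 1L, , ] <- g
  dx
}

# Residual unit: two 3x3 convolutions and two ReLUs with an identity
# shortcut, y = relu(x + conv2(relu(conv1(x)))).
residualLayer <- function(channels) {
  u1 <- initConv(3, 3, channels, channels)
  u2 <- initConv(3, 3, channels, channels)
  list(type = "residual", w1 = u1$w, b1 = u1$b, w2 = u2$w, b2 = u2$b)
}

# Inception module: parallel 1x1, 3x3 and 5x5 convolutions (ReLU) plus a
# 3x3 stride-1 max-pool passthrough, concatenated along channels.
inceptionLayer <- function(cin, c1, c3, c5) {
  b1 <- initConv(1, 1, cin, c1)
  b3 <- initConv(3, 3, cin, c3)
  b5 <- initConv(5, 5, cin, c5)
  list(type = "inception", cin = cin, cout = c1 + c3 + c5 + cin,
       w1 = b1$w, bb1 = b1$b, w3 = b3$w, bb3 = b3$b, w5 = b5$w, bb5 = b5$b)
}

gapLayer <- function() list(type = "gap")

# Per-channel batch normalization of the pooled feature vector (1-D, over
# the batch), with running statistics for inference. Without it the softmax
# head converges impractically slowly at small learning rates: the pooled
# area-fraction features are all-positive with large class-independent
# means and tiny variances. gamma is initialized above 1 so the normalized
# features enter the head at a scale the configured learning rates can use.
bnormLayer <- function(channels, gammaInit = 4) {
  list(type = "bnorm", gamma = rep(gammaInit, channels),
       beta = rep(0, channels), rmean = rep(0, channels),
       rvar = rep(1, channels), eps = 1e-5, momentum = 0.9)
}

# Frozen per-channel standardization of the pooled features:
# y = gain * (f - center) / scale, with center/scale estimated once from
# the training data when training starts and fixed thereafter (serialized
# with the model). Deterministic at every batch size, unlike batch norm.
featNormLayer <- function(channels, gain = 4) {
  list(type = "featnorm", center = rep(0, channels),
       scale = rep(1, channels), gain = gain, initialized = FALSE)
}

denseLayer <- function(cin, cout) {
  list(type = "dense",
       w = matrix(rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout),
       b = rep(0, cout))
}

relu4 <- function(z) { z[z < 0] <- 0; z }

concatChannels <- function(parts) {
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], 1L)
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  off <- 0L
  for (p in parts) {
    k <- dim(p)[3]
    out[, , off + seq_len(k), ] <- p
    off <- off + k
  }
  out
}

nnForwardLayer <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      z <- nn_conv_fw(x, layer$w, layer$b, layer$stride, layer$pad)
      y <- if (layer$relu) relu4(z) else z
      list(y = y, cache = list(x = x, z = z))
    },
    pool = {
      r <- nn_maxpool_fw(x, layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
    },
    avgpool = {
      list(y = avgPoolFw(x), cache = list(xdim = dim(x)))
    },
    residual = {
      z1 <- nn_conv_fw(x, layer$w1, layer$b1, 1L, 1L)
      a1 <- relu4(z1)
      z2 <- nn_conv_fw(a1, layer$w2, layer$b2, 1L, 1L)
      s <- x + z2
      list(y = relu4(s), cache = list(x = x, z1 = z1, a1 = a1, s = s))
    },
    inception = {
      z1 <- nn_conv_fw(x, layer$w1, layer$bb1, 1L, 0L)
      z3 <- nn_conv_fw(x, layer$w3, layer$bb3, 1L, 1L)
      z5 <- nn_conv_fw(x, layer$w5, layer$bb5, 1L, 2L)
      pp <- nn_maxpool_fw(x, 3L, 1L, 1L)
      y <- concatChannels(list(relu4(z1), relu4(z3), relu4(z5), pp$y))
      list(y = y, cache = list(x = x, z1 = z1, z3 = z3, z5 = z5,
                               pidx = pp$idx))
    },
    gap = {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2], d[3] * d[4])
      y <- matrix(colMeans(m), d[3], d[4])
      list(y = y, cache = list(xdim = d))
    },
    bnorm = {
      if (train && ncol(x) > 1) {
        mu <- rowMeans(x)
        v <- rowMeans(x^2) - mu^2
        layer$rmean <- layer$momentum * layer$rmean +
          (1 - layer$momentum) * mu
        layer$rvar <- layer$momentum * layer$rvar +
          (1 - layer$momentum) * v
      } else {
        mu <- layer$rmean
        v <- layer$rvar
      }
      xh <- (x - mu) / sqrt(v + layer$eps)
      list(y = layer$gamma * xh + layer$beta,
           cache = list(xh = xh, v = v), layer = layer)
    },
    featnorm = {
      list(y = layer$gain * (x - layer$center) / layer$scale,
           cache = list())
    },
    dense = {
      z <- crossprod(layer$w, x) + layer$b
      list(y = z, cache = list(x = x))
    },
    stop("unknown layer type"))
}

nnForward <- function(layers, x, keepCache = TRUE, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nnForwardLayer(layers[[i]], x, train = train)
    x <- r$y
    if (keepCache) caches[[i]] <- r$cache
    if (!is.null(r$layer)) layers[[i]] <- r$layer   # bnorm running stats
  }
  list(out = x, caches = caches, layers = layers)
}

nnBackwardLayer <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      dz <- if (layer$relu) dy * (cache$z > 0) else dy
      g <- nn_conv_bw(cache$x, layer$w, dz, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    pool = {
      list(dx = nn_maxpool_bw(dy, cache$idx, as.integer(cache$xdim)),
           grads = NULL)
    },
    avgpool = {
      list(dx = avgPoolBw(dy, cache$xdim), grads = NULL)
    },
    residual = {
      ds <- dy * (cache$s > 0)
      g2 <- nn_conv_bw(cache$a1, layer$w2, ds, 1L, 1L)
      dz1 <- g2$dx * (cache$z1 > 0)
      g1 <- nn_conv_bw(cache$x, layer$w1, dz1, 1L, 1L)
      list(dx = ds + g1$dx,
           grads = list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db))
    },
    inception = {
      d <- dim(cache$z1)
      cs <- c(dim(cache$z1)[3], dim(cache$z3)[3], dim(cache$z5)[3],
              dim(cache$x)[3])
      off <- cumsum(c(0, cs))
      dz1 <- dy[, , off[1] + seq_len(cs[1]), , drop = FALSE] * (cache$z1 > 0)
      dz3 <- dy[, , off[2] + seq_len(cs[2]), , drop = FALSE] * (cache$z3 > 0)
      dz5 <- dy[, , off[3] + seq_len(cs[3]), , drop = FALSE] * (cache$z5 > 0)
      dp <- dy[, , off[4] + seq_len(cs[4]), , drop = FALSE]
      g1 <- nn_conv_bw(cache$x, layer$w1, dz1, 1L, 0L)
      g3 <- nn_conv_bw(cache$x, layer$w3, dz3, 1L, 1L)
      g5 <- nn_conv_bw(cache$x, layer$w5, dz5, 1L, 2L)
      dxp <- nn_maxpool_bw(dp, cache$pidx, as.integer(dim(cache$x)))
      list(dx = g1$dx + g3$dx + g5$dx + dxp,
           grads = list(w1 = g1$dw, bb1 = g1$db, w3 = g3$dw, bb3 = g3$db,
                        w5 = g5$dw, bb5 = g5$db))
    },
    gap = {
      d <- cache$xdim
      per <- d[1] * d[2]
      dx <- array(0, dim = d)
      dx[] <- rep(as.vector(dy), each = per) / per
      list(dx = dx, grads = NULL)
    },
    bnorm = {
      xh <- cache$xh
      dxh <- dy * layer$gamma
      dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) /
        sqrt(cache$v + layer$eps)
      list(dx = dx,
           grads = list(gamma = rowSums(dy * xh), beta = rowSums(dy)))
    },
    featnorm = {
      list(dx = dy * layer$gain / layer$scale, grads = NULL)
    },
    dense = {
      list(dx = layer$w %*% dy,
           grads = list(w = cache$x %*% t(dy), b = rowSums(dy)))
    },
    stop("unknown layer type"))
}

nnBackward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dy <- dlogits
  for (i in rev(seq_along(layers))) {
    r <- nnBackwardLayer(layers[[i]], caches[[i]], dy)
    if (!is.null(r$grads)) grads[[i]] <- r$grads
    dy <- r$dx
  }
  grads
}

softmaxProbs <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# Cross-entropy loss and logit gradient for integer labels 1..K.
softmaxLoss <- function(logits, labels) {
  p <- softmaxProbs(logits)
  n <- ncol(p)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(labels, seq_len(n))] <- dl[cbind(labels, seq_len(n))] - 1
  list(loss = loss, dlogits = dl / n)
}

newVelocities <- function(layers)
  lapply(layers, function(l) {
    pn <- intersect(names(l), c("w", "b", "w1", "b1", "w2", "b2",
                                "w3", "w5", "bb1", "bb3", "bb5",
                                "gamma", "beta"))
    if (!length(pn)) return(NULL)
    stats::setNames(lapply(pn, function(p) l[[p]] * 0), pn)
  })

# One SGD-with-momentum step over all layer parameters. A layer's lrMult
# (default 1) scales its learning rate; 0 freezes it, the fine-tuning
# regime used for structured-initialized feature blocks.
momentumStep <- function(layers, grads, vel, lr, momentum) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    lm <- if (is.null(layers[[i]]$lrMult)) 1 else layers[[i]]$lrMult
    if (lm == 0) next
    for (p in names(g)) {
      gi <- g[[p]]
      dim(gi) <- dim(vel[[i]][[p]])
      vel[[i]][[p]] <- momentum * vel[[i]][[p]] - lr * lm * gi
      layers[[i]][[p]] <- layers[[i]][[p]] + vel[[i]][[p]]
    }
  }
  list(layers = layers, vel = vel)
}

# Estimate featnorm center/scale from up to maxN training samples by a
# forward pass through the layers below it; frozen thereafter.
initFeatNorm <- function(layers, X, maxN = 160L) {
  fi <- which(vapply(layers, function(l) l$type == "featnorm", TRUE))
  if (!length(fi) || isTRUE(layers[[fi]]$initialized)) return(layers)
  n <- dim(X)[4]
  idx <- if (n > maxN) round(seq(1, n, length.out = maxN)) else seq_len(n)
  feats <- NULL
  for (start in seq(1, length(idx), by = 32)) {
    sub <- idx[start:min(start + 31, length(idx))]
    fw <- nnForward(layers[seq_len(fi - 1)], X[, , , sub, drop = FALSE],
                    keepCache = FALSE)
    feats <- cbind(feats, fw$out)
  }
  layers[[fi]]$center <- rowMeans(feats)
  layers[[fi]]$scale <- pmax(apply(feats, 1, stats::sd), 1e-3)
  layers[[fi]]$initialized <- TRUE
  layers
}

# Core training loop; X is [S,S,1,n], y integer labels. Returns updated
# layers, a log, and a divergence flag.
nnTrainLoop <- function(layers, X, y, steps, lr, momentum, batchSize,
                        vel = NULL, valX = NULL, valY = NULL,
                        logEvery = 50L) {
  n <- dim(X)[4]
  if (is.null(vel)) vel <- newVelocities(layers)
  log <- data.frame(step = integer(), loss = numeric(),
                    valAccuracy = numeric())
  diverged <- FALSE
  lastFinite <- layers
  for (s in seq_len(steps)) {
    idx <- sample.int(n, batchSize, replace = batchSize > n)
    xb <- X[, , , idx, drop = FALSE]
    fw <- nnForward(layers, xb, train = TRUE)
    layers <- fw$layers                     # bnorm running statistics
    sl <- softmaxLoss(fw$out, y[idx])
    if (!is.finite(sl$loss)) {
      # revert to the weights that produced the last finite loss so the
      # model remains evaluable after divergence
      diverged <- TRUE
      layers <- lastFinite
      log <- rbind(log, data.frame(step = s, loss = sl$loss,
                                   valAccuracy = NA_real_))
      break
    }
    lastFinite <- layers
    grads <- nnBackward(layers, fw$caches, sl$dlogits)
    up <- momentumStep(layers, grads, vel, lr, momentum)
    layers <- up$layers; vel <- up$vel
    va <- NA_real_
    if ((s %% logEvery == 0 || s == steps) && !is.null(valX))
      va <- nnAccuracy(layers, valX, valY)
    log <- rbind(log, data.frame(step = s, loss = sl$loss,
                                 valAccuracy = va))
  }
  list(layers = layers, vel = vel, log = log, diverged = diverged)
}

nnPredictProbs <- function(layers, X, chunk = 32L) {
  n <- dim(X)[4]
  out <- matrix(NA_real_, 3, n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- nnForward(layers, X[, , , idx, drop = FALSE], keepCache = FALSE)
    out[, idx] <- softmaxProbs(fw$out)
  }
  out
}

nnAccuracy <- function(layers, X, y) {
  p <- nnPredictProbs(layers, X)
  mean(apply(p, 2, which.max) == y)
}
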