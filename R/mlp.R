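# Dense-network core for the hyperparameter classifier heads.
#
# Small fully connected nets (10 -> 32 -> 16 -> K) trained with minibatch
# Adam on cross-entropy; written directly in R matrix algebra. Forward,
# backward and the optimizer live here; head semantics live in heads.R.
# Weight matrices are (in x out); activations X %*% W + b row-wise.

.LRELU_ALPHA <- 0.01

applyActivation <- function(z, kind) {
  switch(kind,
    lrelu = ifelse(z > 0, z, .LRELU_ALPHA * z),
    relu = pmax(z, 0),
    linear = z,
    stop("unknown activation: ", kind)
  )
}

activationGrad <- function(z, kind) {
  switch(kind,
    lrelu = ifelse(z > 0, 1, .LRELU_ALPHA),
    relu = (z > 0) * 1,
    linear = matrix(1, nrow(z), ncol(z)),
    stop("unknown activation: ", kind)
  )
}

# He-uniform initialisation; draws from the current RNG stream.
mlpInit <- function(spec) {
  dims <- c(spec$inputDim, spec$hidden, spec$outDim)
  weights <- vector("list", length(dims) - 1)
  for (i in seq_along(weights)) {
    fanIn <- dims[i]
    lim <- sqrt(6 / fanIn)
    weights[[i]] <- list(
      W = matrix(stats::runif(fanIn * dims[i + 1], -lim, lim), fanIn, dims[i + 1]),
      b = rep(0, dims[i + 1])
    )
  }
  weights
}

# Forward pass. X: n x inputDim. Returns logits and per-layer caches.
# Dropout (inverted) is applied only when train = TRUE; masks use the RNG.
mlpForward <- function(weights, spec, X, train = FALSE) {
  acts <- spec$activations # length = number of hidden layers
  drops <- spec$dropout
  caches <- vector("list", length(weights))
  A <- X
  for (i in seq_along(weights)) {
    Z <- sweep(A %*% weights[[i]]$W, 2, weights[[i]]$b, "+")
    if (i < length(weights)) {
      H <- applyActivation(Z, acts[i])
      mask <- NULL
      p <- drops[i]
      if (train && p > 0) {
        mask <- matrix(stats::runif(length(H)) >= p, nrow(H), ncol(H)) / (1 - p)
        H <- H * mask
      }
      caches[[i]] <- list(input = A, Z = Z, mask = mask)
      A <- H
    } else {
      caches[[i]] <- list(input = A, Z = Z, mask = NULL)
      A <- Z # linear logits
    }
  }
  list(logits = A, caches = caches)
}

softmaxRows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Mean cross-entropy of integer class targets (1-based).
crossEntropy <- function(logits, y) {
  p <- softmaxRows(logits)
  -mean(log(pmax(p[cbind(seq_along(y), y)], 1e-12)))
}

# Backward pass for mean cross-entropy. Returns per-layer gradients.
mlpBackward <- function(weights, spec, fwd, y) {
  n <- nrow(fwd$logits)
  P <- softmaxRows(fwd$logits)
  Y <- matrix(0, n, ncol(P))
  Y[cbind(seq_len(n), y)] <- 1
  delta <- (P - Y) / n
  grads <- vector("list", length(weights))
  for (i in rev(seq_along(weights))) {
    cache <- fwd$caches[[i]]
    grads[[i]] <- list(
      W = crossprod(cache$input, delta),
      b = colSums(delta)
    )
    if (i > 1) {
      back <- delta %*% t(weights[[i]]$W)
      prev <- fwd$caches[[i - 1]]
      if (!is.null(prev$mask)) back <- back * prev$mask
      delta <- back * activationGrad(prev$Z, spec$activations[i - 1])
    }
  }
  grads
}

adamInit <- function(weights) {
  lapply(weights, function(l) {
    list(
      mW = l$W * 0, vW = l$W * 0,
      mb = l$b * 0, vb = l$b * 0
    )
  })
}

# One Adam step with decoupled L2 ("weight decay" added to the gradient).
adamStep <- function(weights, grads, state, t, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (i in seq_along(weights)) {
    gW <- grads[[i]]$W + weightDecay * weights[[i]]$W
    gb <- grads[[i]]$b
    state[[i]]$mW <- beta1 * state[[i]]$mW + (1 - beta1) * gW
    state[[i]]$vW <- beta2 * state[[i]]$vW + (1 - beta2) * gW * gW
    state[[i]]$mb <- beta1 * state[[i]]$mb + (1 - beta1) * gb
    state[[i]]$vb <- beta2 * state[[i]]$vb + (1 - beta2) * gb * gb
    weights[[i]]$W <- weights[[i]]$W - lr * (state[[i]]$mW / corr1) /
      (sqrt(state[[i]]$vW / corr2) + eps)
    weights[[i]]$b <- weights[[i]]$b - lr * (state[[i]]$mb / corr1) /
      (sqrt(state[[i]]$vb / corr2) + eps)
  }
  list(weights = weights, state = state)
}

# Full training loop. X/y: training rows and 1-based class indices;
# Xval/yval: validation split for early stopping (NULL disables it).
# Deterministic given the ambient RNG state (callers use withSeed).
trainMLP <- function(spec, X, y, Xval = NULL, yval = NULL,
                     epochs = 1500, batchSize = 5, patience = 100) {
  weights <- mlpInit(spec)
  state <- adamInit(weights)
  n <- nrow(X)
  t <- 0
  bestVal <- Inf
  bestWeights <- weights
  bestEpoch <- 0
  sinceBest <- 0
  log <- matrix(NA_real_, epochs, 2, dimnames = list(NULL, c("train_loss", "val_loss")))
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batchSize)
    epochLoss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batchSize - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- mlpForward(weights, spec, Xb, train = TRUE)
      loss <- crossEntropy(fwd$logits, yb)
      if (!is.finite(loss)) stop("NaN/Inf training loss at epoch ", epoch)
      epochLoss <- epochLoss + loss * length(idx)
      grads <- mlpBackward(weights, spec, fwd, yb)
      t <- t + 1
      upd <- adamStep(weights, grads, state, t, spec$lr, spec$weightDecay)
      weights <- upd$weights
      state <- upd$state
    }
    log[epoch, "train_loss"] <- epochLoss / n
    if (!is.null(Xval)) {
      valLoss <- crossEntropy(mlpForward(weights, spec, Xval, train = FALSE)$logits, yval)
      if (!is.finite(valLoss)) stop("NaN/Inf validation loss at epoch ", epoch)
      log[epoch, "val_loss"] <- valLoss
      if (valLoss < bestVal - 1e-12) {
        bestVal <- valLoss
        bestWeights <- weights
        bestEpoch <- epoch
        sinceBest <- 0
      } else {
        sinceBest <- sinceBest + 1
        if (sinceBest >= patience) break
      }
    } else {
      bestWeights <- weights
      bestEpoch <- epoch
    }
  }
  done <- !is.na(log[, "train_loss"])
  # strip incidental dimnames picked up from feature-named inputs, so that
  # checkpoints round-trip exactly
  bestWeights <- lapply(bestWeights, function(l) list(W = unname(l$W), b = unname(l$b)))
  list(
    weights = bestWeights, bestEpoch = bestEpoch,
    log = data.frame(epoch = which(done), log[done, , drop = FALSE])
  )
}

# Class probabilities for a weight set (dropout off).
mlpPredictProba <- function(weights, spec, X) {
  softmaxRows(mlpForward(weights, spec, X, train = FALSE)$logits)
}

# Gradient of one class's logit with respect to the input vector x.
# Used by integrated gradients; dropout off, softmax excluded (the score is
# the pre-softmax logit, for which the linear-model closed form holds).
mlpInputGradient <- function(weights, spec, x, class) {
  X <- matrix(x, nrow = 1)
  fwd <- mlpForward(weights, spec, X, train = FALSE)
  delta <- matrix(0, 1, ncol(fwd$logits))
  delta[1, class] <- 1
  for (i in rev(seq_along(weights))) {
    back <- delta %*% t(weights[[i]]$W)
    if (i > 1) {
      prev <- fwd$caches[[i - 1]]
      delta <- back * activationGrad(prev$Z, spec$activations[i - 1])
    } else {
      delta <- back
    }
  }
  as.numeric(delta)
}

# Logit of one class at input x.
mlpLogit <- function(weights, spec, x, class) {
  mlpForward(weights, spec, matrix(x, nrow = 1), train = FALSE)$logits[1, class]
}
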