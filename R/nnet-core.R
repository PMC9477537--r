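# Minimal dense / 1-D convolution machinery with hand-written backprop and
# Adam. Everything is plain base-R linear algebra so training is exactly
# reproducible given a seed. Batches are N x L x C arrays (channels last).

channel_mat <- function(arr, c) {
  m <- arr[, , c, drop = FALSE]
  dim(m) <- dim(arr)[1:2]
  m
}

# W: F x (C*K), column (c-1)*K + j holds kernel tap j of input channel c.
conv1d_fwd <- function(X, W, b, K) {
  N <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  nf <- nrow(W); Lout <- L - K + 1L
  out <- array(0, c(N, Lout, nf))
  chans <- lapply(seq_len(C), channel_mat, arr = X)
  for (f in seq_len(nf)) {
    O <- matrix(b[f], N, Lout)
    for (c in seq_len(C)) {
      M <- chans[[c]]
      for (j in seq_len(K))
        O <- O + W[f, (c - 1L) * K + j] * M[, j:(j + Lout - 1L), drop = FALSE]
    }
    out[, , f] <- O
  }
  out
}

conv1d_bwd <- function(dOut, X, W, K) {
  N <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  nf <- nrow(W); Lout <- L - K + 1L
  dW <- matrix(0, nf, ncol(W)); db <- numeric(nf)
  dX <- array(0, c(N, L, C))
  chans <- lapply(seq_len(C), channel_mat, arr = X)
  for (f in seq_len(nf)) {
    G <- channel_mat(dOut, f)
    db[f] <- sum(G)
    for (c in seq_len(C)) {
      M <- chans[[c]]
      dM <- matrix(0, N, L)
      for (j in seq_len(K)) {
        idx <- j:(j + Lout - 1L)
        dW[f, (c - 1L) * K + j] <- sum(G * M[, idx, drop = FALSE])
        dM[, idx] <- dM[, idx] + W[f, (c - 1L) * K + j] * G
      }
      dX[, , c] <- dX[, , c] + dM
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# Non-overlapping average pooling along the length axis; a trailing
# remainder shorter than `p` is dropped.
avgpool_fwd <- function(X, p) {
  N <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  W <- L %/% p
  out <- array(0, c(N, W, C))
  for (c in seq_len(C)) {
    M <- channel_mat(X, c)
    O <- matrix(0, N, W)
    for (o in seq_len(p))
      O <- O + M[, seq(o, by = p, length.out = W), drop = FALSE]
    out[, , c] <- O / p
  }
  out
}

avgpool_bwd <- function(dOut, p, L) {
  N <- dim(dOut)[1]; W <- dim(dOut)[2]; C <- dim(dOut)[3]
  dX <- array(0, c(N, L, C))
  for (c in seq_len(C)) {
    G <- channel_mat(dOut, c) / p
    for (o in seq_len(p))
      dX[, seq(o, by = p, length.out = W), c] <- G
  }
  dX
}

relu <- function(x) x * (x > 0)

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- shape network: fixed small 1-D CNN ------------------------------------
# 2000 -> avgpool 8 -> 250 -> [conv 9x8, relu, avgpool 5] -> 48x8
#      -> [conv 5x8, relu, avgpool 4] -> 11x8 -> flatten 88
#      -> dense 16 relu -> dense 1 sigmoid

SHAPE_ARCH <- list(input_len = 2000L, pre_pool = 8L,
                   f1 = 8L, k1 = 9L, pool1 = 5L,
                   f2 = 8L, k2 = 5L, pool2 = 4L,
                   hidden = 16L)

shape_init_params <- function(arch = SHAPE_ARCH) {
  l0 <- arch$input_len %/% arch$pre_pool
  l1 <- (l0 - arch$k1 + 1L) %/% arch$pool1
  l2 <- (l1 - arch$k2 + 1L) %/% arch$pool2
  flat <- l2 * arch$f2
  list(W1 = glorot(arch$f1, arch$k1), b1 = numeric(arch$f1),
       W2 = glorot(arch$f2, arch$f1 * arch$k2), b2 = numeric(arch$f2),
       W3 = glorot(arch$hidden, flat), b3 = numeric(arch$hidden),
       W4 = glorot(1L, arch$hidden), b4 = numeric(1L))
}

shape_forward <- function(params, X, arch = SHAPE_ARCH, cache = FALSE) {
  N <- nrow(X)
  X3 <- array(X, c(N, ncol(X), 1L))
  a0 <- avgpool_fwd(X3, arch$pre_pool)
  z1 <- conv1d_fwd(a0, params$W1, params$b1, arch$k1)
  p1 <- avgpool_fwd(relu(z1), arch$pool1)
  z2 <- conv1d_fwd(p1, params$W2, params$b2, arch$k2)
  p2 <- avgpool_fwd(relu(z2), arch$pool2)
  flat <- matrix(p2, N, dim(p2)[2] * dim(p2)[3])
  z3 <- flat %*% t(params$W3) + rep(params$b3, each = N)
  h <- relu(z3)
  logit <- h %*% t(params$W4) + params$b4
  prob <- stats::plogis(as.numeric(logit))
  if (!cache) return(prob)
  list(prob = prob, a0 = a0, z1 = z1, p1 = p1, z2 = z2, p2 = p2,
       flat = flat, z3 = z3, h = h)
}

shape_backward <- function(params, cache, y, arch = SHAPE_ARCH) {
  N <- length(y)
  dlogit <- matrix((cache$prob - y) / N, N, 1L)
  dW4 <- t(dlogit) %*% cache$h
  db4 <- colSums(dlogit)
  dh <- (dlogit %*% params$W4) * (cache$z3 > 0)
  dW3 <- t(dh) %*% cache$flat
  db3 <- colSums(dh)
  dflat <- dh %*% params$W3
  dp2 <- array(dflat, dim(cache$p2))
  dr2 <- avgpool_bwd(dp2, arch$pool2, dim(cache$z2)[2])
  dz2 <- dr2 * (cache$z2 > 0)
  g2 <- conv1d_bwd(dz2, cache$p1, params$W2, arch$k2)
  dr1 <- avgpool_bwd(g2$dX, arch$pool1, dim(cache$z1)[2])
  dz1 <- dr1 * (cache$z1 > 0)
  g1 <- conv1d_bwd(dz1, cache$a0, params$W1, arch$k1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

# Generic minibatch trainer with a fixed validation split and early
# stopping on validation loss; restores the best-epoch weights.
train_net <- function(params, fwd, bwd, X, y, seed,
                      epochs = 150L, batch = 32L, lr = 1e-3,
                      val_frac = 0.2, patience = 10L) {
  n <- if (is.matrix(X)) nrow(X) else length(y)
  with_seed(seed, {
    idx <- sample.int(n)
    n_val <- max(1L, floor(val_frac * n))
    val <- idx[seq_len(n_val)]
    trn <- idx[-seq_len(n_val)]
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(trn)
      for (b0 in seq(1L, length(ord), by = batch)) {
        bi <- ord[b0:min(b0 + batch - 1L, length(ord))]
        cache <- fwd(params, X[bi, , drop = FALSE], cache = TRUE)
        grads <- bwd(params, cache, y[bi])
        upd <- adam_step(params, grads, state, lr = lr)
        params <- upd$params; state <- upd$state
      }
      vloss <- bce_loss(fwd(params, X[val, , drop = FALSE]), y[val])
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    best
  })
}

# ---- combiner MLP: 13 inputs -> hidden relu -> sigmoid ---------------------

mlp_init_params <- function(n_in, hidden = 8L) {
  list(W1 = glorot(hidden, n_in), b1 = numeric(hidden),
       W2 = glorot(1L, hidden), b2 = numeric(1L))
}

mlp_forward <- function(params, X, cache = FALSE) {
  N <- nrow(X)
  z1 <- X %*% t(params$W1) + rep(params$b1, each = N)
  h <- relu(z1)
  logit <- h %*% t(params$W2) + params$b2
  prob <- stats::plogis(as.numeric(logit))
  if (!cache) return(prob)
  list(prob = prob, X = X, z1 = z1, h = h)
}

mlp_backward <- function(params, cache, y) {
  N <- length(y)
  dlogit <- matrix((cache$prob - y) / N, N, 1L)
  dW2 <- t(dlogit) %*% cache$h
  db2 <- colSums(dlogit)
  dh <- (dlogit %*% params$W2) * (cache$z1 > 0)
  list(W1 = t(dh) %*% cache$X, b1 = colSums(dh), W2 = dW2, b2 = db2)
}
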