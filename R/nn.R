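# Minimal neural-network primitives for the 1D-convolutional autoencoder and
# classifier. Activations with a temporal axis are stored position-major: a
# batch of n sequences of length L with C channels is an (n*L) x C matrix
# whose row block t holds all n samples at time t. In this layout a
# kernel-2 "same"-padded convolution is two matrix products, max-pooling is
# row indexing, and batch-norm is column statistics, so everything runs
# through BLAS.


# Fast column-wise recycling helpers (avoid sweep()'s aperm copies).
col_add <- function(X, v) X + rep(v, rep.int(nrow(X), length(v)))
col_sub <- function(X, v) X - rep(v, rep.int(nrow(X), length(v)))
col_mul <- function(X, v) X * rep(v, rep.int(nrow(X), length(v)))

# Kernel-2, stride-1, "same"-padded 1D convolution (compiled kernel).
# A: (n*L) x C_in. W1, W2: C_in x C_out (taps at t and t+1). b: C_out.
nn_conv_fwd <- function(A, n, W1, W2, b) {
  list(Z = cpp_conv_fwd(A, n, W1, W2, b), A = A, n = n)
}

# Convolution with fused ReLU; Z is the post-activation map and doubles as
# the ReLU mask in the fused pool backward.
nn_conv_relu_fwd <- function(A, n, W1, W2, b) {
  list(Z = cpp_conv_relu_fwd(A, n, W1, W2, b), A = A, n = n)
}

nn_conv_bwd <- function(cache, dZ, W1, W2, n, need_dA = TRUE) {
  out <- cpp_conv_bwd(cache$A, dZ, W1, W2, n, need_dA)
  out$db <- as.vector(out$db)
  out
}

nn_relu_fwd <- function(Z) {
  cpp_relu_fwd(Z)
}

nn_relu_bwd <- function(dA, Z) {
  cpp_relu_bwd(dA, Z)
}

# Non-overlapping size-2 max pooling along time; odd trailing position is
# dropped. Returns pooled activations plus the cache needed for backprop.
nn_pool_fwd <- function(A, n, L) {
  out <- cpp_pool_fwd(A, n, L)
  out$n <- n
  out$L <- L
  out
}

nn_pool_bwd <- function(cache, dP) {
  cpp_pool_bwd(dP, cache$take1, cache$n, cache$L)
}

# Fused pool + ReLU backward; A_post is the post-ReLU activation that fed
# the pool.
nn_pool_relu_bwd <- function(cache, dP, A_post) {
  cpp_pool_relu_bwd(dP, cache$take1, A_post, cache$n, cache$L)
}

# Batch normalization over rows, per column (= per channel x all positions
# and samples). Population statistics are tracked as running averages for
# inference.
nn_bn_fwd <- function(X, gamma, beta, running, training, momentum = 0.1,
                      eps = 1e-5) {
  out <- cpp_bn_fwd(X, gamma, beta, running$mean, running$var,
                    compute_stats = training, eps = eps)
  if (training) {
    running$mean <- (1 - momentum) * running$mean + momentum * as.vector(out$mu)
    running$var <- (1 - momentum) * running$var + momentum * as.vector(out$var)
  }
  list(Y = out$Y, xhat = out$xhat, inv_std = as.vector(out$inv_std),
       running = running)
}

nn_bn_bwd <- function(cache, dY, gamma) {
  out <- cpp_bn_bwd(dY, cache$xhat, cache$inv_std, gamma)
  list(dX = out$dX, dgamma = as.vector(out$dgamma),
       dbeta = as.vector(out$dbeta))
}

# Backward through batch norm with FROZEN statistics (inference-mode
# normalization treated as a fixed per-channel affine map).
nn_bn_bwd_frozen <- function(cache, dY, gamma) {
  list(
    dX = col_mul(dY, gamma * cache$inv_std),
    dgamma = colSums(dY * cache$xhat),
    dbeta = colSums(dY)
  )
}

# Inverted dropout: scaling happens at train time, inference is identity.
# Draws use R's RNG stream, so set.seed() governs the masks.
nn_dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(Y = X, mask = NULL))
  }
  cpp_dropout_fwd(X, p)
}

nn_dropout_bwd <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

nn_dense_fwd <- function(X, W, b) {
  col_add(X %*% W, b)
}

nn_dense_bwd <- function(X, W, dY) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = dY %*% t(W))
}

nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean softmax cross-entropy and its logit gradient. y: integer class 1..K.
nn_softmax_ce <- function(logits, y) {
  P <- nn_softmax(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = P)
}

# He-uniform initialization for a fan_in x fan_out weight matrix.
nn_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Adam optimizer over a named list of parameter arrays.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Reshape a batch matrix (n x L) into position-major (n*L) x 1 and back.
to_posmajor <- function(X) {
  dim(X) <- c(length(X), 1L)
  X
}

# Flatten a position-major (n*Lout) x C activation into an n x (Lout*C)
# feature matrix (fixed but arbitrary feature order).
nn_flatten <- function(A, n) {
  dim(A) <- c(n, length(A) %/% n)
  A
}

nn_unflatten <- function(F, n, C) {
  dim(F) <- c(length(F) %/% C, C)
  F
}
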