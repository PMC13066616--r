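# Compact neural-network engine: batched forward/backward passes for the
# three sequence classifiers, written against base matrix algebra. All
# gradients are hand-derived and guarded by finite-difference tests.
#
# Conventions: a batch of windows is an array (n, T, C); flattening an
# (n, T, C) array with matrix(x, n*T, C) orders rows sample-fastest, which
# every helper below relies on.

leaky_relu <- function(x, alpha = 0.01) {
  ifelse(x > 0, x, alpha * x)
}

leaky_relu_grad <- function(x, alpha = 0.01) {
  ifelse(x > 0, 1, alpha)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Weighted binary cross-entropy on logits.
# loss_i = pw * y * softplus(-z) + (1 - y) * softplus(z); returns mean loss
# and d(mean loss)/dz.
bce_logits <- function(z, y, pos_weight = 1) {
  y <- as.numeric(y)
  loss <- mean(pos_weight * y * softplus(-z) + (1 - y) * softplus(z))
  dz <- (-pos_weight * y * sigmoid(-z) + (1 - y) * sigmoid(z)) / length(z)
  list(loss = loss, dz = dz)
}

# ---- 1-d convolution over the time axis (same padding) ----------------------

pad_time <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  out[, pad + seq_len(d[2]), ] <- x
  out
}

im2col <- function(xp, T_out, k) {
  n <- dim(xp)[1]; C <- dim(xp)[3]
  M <- matrix(0, n * T_out, k * C)
  for (j in seq_len(k)) {
    M[, (j - 1) * C + seq_len(C)] <- matrix(xp[, j:(j + T_out - 1), , drop = FALSE],
                                            n * T_out, C)
  }
  M
}

# W: (k*C_in) x C_out, b: C_out. Same-length output via symmetric padding.
conv1d_fwd <- function(x, W, b, k) {
  n <- dim(x)[1]; T_len <- dim(x)[2]
  pad <- (k - 1) %/% 2
  xp <- pad_time(x, pad)
  M <- im2col(xp, T_len, k)
  out_flat <- M %*% W
  out_flat <- sweep(out_flat, 2, b, `+`)
  out <- array(out_flat, c(n, T_len, ncol(W)))
  list(out = out, M = M, n = n, T_len = T_len, k = k, pad = pad,
       C_in = dim(x)[3])
}

conv1d_bwd <- function(cache, W, dout) {
  n <- cache$n; T_len <- cache$T_len; k <- cache$k; pad <- cache$pad
  C_in <- cache$C_in
  dflat <- matrix(dout, n * T_len, dim(dout)[3])
  dW <- crossprod(cache$M, dflat)
  db <- colSums(dflat)
  dM <- dflat %*% t(W)
  dxp <- array(0, c(n, T_len + 2 * pad, C_in))
  for (j in seq_len(k)) {
    dxs <- array(dM[, (j - 1) * C_in + seq_len(C_in)], c(n, T_len, C_in))
    dxp[, j:(j + T_len - 1), ] <-
      dxp[, j:(j + T_len - 1), , drop = FALSE] + dxs
  }
  dx <- dxp[, pad + seq_len(T_len), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- max pooling over time (kernel 3, stride 1, same padding) ---------------

maxpool1d_fwd <- function(x, k = 3L) {
  n <- dim(x)[1]; T_len <- dim(x)[2]; C <- dim(x)[3]
  pad <- (k - 1) %/% 2
  xp <- pad_time(x, pad)
  xp[, c(seq_len(pad), T_len + pad + seq_len(pad)), ] <- -Inf
  out <- array(-Inf, dim(x))
  amax <- array(1L, dim(x))   # offset (1..k) achieving the max
  for (j in seq_len(k)) {
    slab <- xp[, j:(j + T_len - 1), , drop = FALSE]
    better <- slab > out
    out[better] <- slab[better]
    amax[better] <- j
  }
  list(out = out, amax = amax, k = k, pad = pad)
}

maxpool1d_bwd <- function(cache, dout) {
  d <- dim(dout); n <- d[1]; T_len <- d[2]
  pad <- cache$pad
  dxp <- array(0, c(n, T_len + 2 * pad, d[3]))
  for (j in seq_len(cache$k)) {
    sel <- cache$amax == j
    slab <- array(0, d)
    slab[sel] <- dout[sel]
    dxp[, j:(j + T_len - 1), ] <- dxp[, j:(j + T_len - 1), , drop = FALSE] + slab
  }
  dxp[, pad + seq_len(T_len), , drop = FALSE]
}

# ---- global average pooling over time ---------------------------------------

gap_fwd <- function(x) {
  n <- dim(x)[1]; T_len <- dim(x)[2]; C <- dim(x)[3]
  out <- matrix(colMeans(matrix(aperm(x, c(2, 1, 3)), T_len, n * C)), n, C)
  list(out = out, T_len = T_len)
}

gap_bwd <- function(cache, dout) {
  n <- nrow(dout); C <- ncol(dout); T_len <- cache$T_len
  dx <- array(0, c(n, T_len, C))
  for (t in seq_len(T_len)) dx[, t, ] <- dout / T_len
  dx
}

# ---- dense layer ------------------------------------------------------------

dense_fwd <- function(x, W, b) {
  out <- x %*% W
  sweep(out, 2, b, `+`)
}

dense_bwd <- function(x, W, dout) {
  list(dx = dout %*% t(W), dW = crossprod(x, dout), db = colSums(dout))
}

# ---- inverted dropout -------------------------------------------------------

dropout_mask <- function(dim_, p, training) {
  if (!training || p <= 0) return(NULL)
  array(rbinom(prod(dim_), 1, 1 - p) / (1 - p), dim_)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# ---- parameter initialization ----------------------------------------------

he_init <- function(nrow_, ncol_, fan_in) {
  matrix(rnorm(nrow_ * ncol_, sd = sqrt(2 / fan_in)), nrow_, ncol_)
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(params, method) {
  state <- list(method = method, t = 0)
  zeros <- map(params, function(p) array(0, dim(p) %||% length(p)))
  if (method == "sgd") {
    state$v <- zeros
  } else {
    state$m <- zeros
    state$v <- zeros
  }
  state
}

# One update over all trainable parameters. `frozen` is a character vector of
# parameter names to skip. SGD uses classic momentum with L2 weight decay
# folded into the gradient; AdamW uses decoupled weight decay.
opt_step <- function(params, grads, state, lr, frozen = character(),
                     momentum = 0.85, weight_decay = 1e-4,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     adamw_decay = 0.01) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    p <- params[[nm]]
    if (state$method == "sgd") {
      g <- g + weight_decay * p
      state$v[[nm]] <- momentum * state$v[[nm]] + g
      params[[nm]] <- p - lr * state$v[[nm]]
    } else {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]] / (1 - beta2^state$t)
      params[[nm]] <- p - lr * (mhat / (sqrt(vhat) + eps) + adamw_decay * p)
    }
  }
  list(params = params, state = state)
}

# Plateau scheduler bookkeeping: multiply lr by `factor` when the validation
# loss has not improved on its best for `patience` consecutive epochs, with a
# hard floor at `min_lr`. Returns the updated tracker.
plateau_step <- function(tracker, val_loss, factor, patience, min_lr) {
  if (val_loss < tracker$best - 1e-12) {
    tracker$best <- val_loss
    tracker$stale <- 0L
  } else {
    tracker$stale <- tracker$stale + 1L
    if (tracker$stale >= patience) {
      tracker$lr <- max(tracker$lr * factor, min_lr)
      tracker$stale <- 0L
    }
  }
  tracker
}

new_plateau <- function(lr) list(lr = lr, best = Inf, stale = 0L)
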