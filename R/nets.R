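#' Specify a sequence-classifier architecture
#'
#' Three compact architectures for 6-hour feature windows, each split into an
#' embedding stage and a classification head so that domain-adaptation
#' losses can align embeddings and fine-tuning can freeze everything before
#' the head. All use the Leaky ReLU activation.
#'
#' * `cnn` — stacked same-padding 1-d convolutions over time (kernel 3,
#'   channels `conv_channels`), global average pooling; dropout 0.5 before
#'   the head.
#' * `lstm` — `lstm_layers` stacked LSTM layers of `hidden` units; the
#'   embedding is the final hidden state; per-layer dropout.
#' * `inceptiontime` — `depth` (default 12) serially composed inception
#'   modules (bottleneck + parallel kernels 3/5/7 + max-pool branch,
#'   residual shortcut every third module), global average pooling;
#'   dropout 0.3 before the head.
#'
#' @param arch `"cnn"`, `"lstm"`, or `"inceptiontime"`.
#' @param dropout Dropout probability (defaults: cnn 0.5, inceptiontime 0.3,
#'   lstm 0.3 per layer).
#' @param conv_channels Integer vector of CNN block widths (default
#'   `c(32, 64, 64)`).
#' @param hidden LSTM hidden size (default 64).
#' @param lstm_layers Number of LSTM layers (default 2).
#' @param depth InceptionTime depth in modules (default 12).
#' @param filters InceptionTime per-branch filter count (default 8; the
#'   embedding width is `4 * filters`).
#' @param bottleneck InceptionTime bottleneck width (default 8).
#' @param extra_dropout Apply dropout inside the embedding stage as well
#'   (after each CNN block / each inception module), as used by the
#'   retraining strategy's regularization. Default `FALSE`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(arch = c("cnn", "lstm", "inceptiontime"),
                       dropout = NULL,
                       conv_channels = c(32L, 64L, 64L),
                       hidden = 64L, lstm_layers = 2L,
                       depth = 12L, filters = 8L, bottleneck = 8L,
                       extra_dropout = FALSE) {
  arch <- match.arg(arch)
  if (is.null(dropout)) {
    dropout <- switch(arch, cnn = 0.5, lstm = 0.3, inceptiontime = 0.3)
  }
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  if (depth < 1) abort("depth must be >= 1")
  structure(list(arch = arch, dropout = dropout,
                 conv_channels = as.integer(conv_channels),
                 hidden = as.integer(hidden), lstm_layers = as.integer(lstm_layers),
                 depth = as.integer(depth), filters = as.integer(filters),
                 bottleneck = as.integer(bottleneck),
                 extra_dropout = isTRUE(extra_dropout)),
            class = "model_spec")
}

#' Build an untrained model
#'
#' Initializes parameters deterministically from `seed` for the given window
#' shape. The returned model exposes the embedding/classifier split through
#' [embed_windows()] and [predict_scores()].
#'
#' @param spec A [model_spec()].
#' @param window_shape `c(hours, channels)` of the windows the model will
#'   consume.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `sepshift_model`.
#' @export
build_model <- function(spec, window_shape, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), length(window_shape) == 2)
  T_len <- as.integer(window_shape[1]); C <- as.integer(window_shape[2])
  set.seed(seed)
  params <- switch(spec$arch,
    cnn = init_cnn(spec, C),
    lstm = init_lstm(spec, C),
    inceptiontime = init_inception(spec, C)
  )
  structure(list(spec = spec, params = params$params,
                 embed_params = params$embed_params,
                 embed_dim = params$embed_dim,
                 window_shape = c(T_len, C), seed = as.integer(seed)),
            class = "sepshift_model")
}

#' @export
print.sepshift_model <- function(x, ...) {
  n_par <- sum(map_int(x$params, ~ length(.x)))
  cat("<sepshift_model> ", x$spec$arch, ", ", n_par, " parameters, windows ",
      x$window_shape[1], "x", x$window_shape[2], "\n", sep = "")
  if (!is.null(x$history)) {
    cat("  trained ", nrow(x$history), " epochs, best epoch ", x$best_epoch,
        " (val loss ", signif(x$best_val_loss, 4), ")\n", sep = "")
  }
  invisible(x)
}

# ---- CNN --------------------------------------------------------------------

init_cnn <- function(spec, C) {
  ch <- spec$conv_channels
  k <- 3L
  params <- list()
  c_in <- C
  for (i in seq_along(ch)) {
    params[[paste0("convW", i)]] <- he_init(k * c_in, ch[i], k * c_in)
    params[[paste0("convb", i)]] <- rep(0, ch[i])
    c_in <- ch[i]
  }
  params$headW <- he_init(c_in, 1L, c_in)
  params$headb <- 0
  list(params = params,
       embed_params = grep("^conv", names(params), value = TRUE),
       embed_dim = c_in)
}

fwd_cnn <- function(model, x, training = FALSE) {
  spec <- model$spec; p <- model$params
  caches <- list(); acts <- list()
  h <- x
  for (i in seq_along(spec$conv_channels)) {
    cv <- conv1d_fwd(h, p[[paste0("convW", i)]], p[[paste0("convb", i)]], 3L)
    caches[[i]] <- cv
    acts[[i]] <- cv$out
    h <- leaky_relu(cv$out)
    if (spec$extra_dropout) {
      msk <- dropout_mask(dim(h), spec$dropout, training)
      caches[[i]]$extra_mask <- msk
      h <- apply_mask(h, msk)
    }
    caches[[i]]$post <- h
  }
  g <- gap_fwd(h)
  embed <- g$out
  msk <- dropout_mask(dim(embed), spec$dropout, training)
  eh <- apply_mask(embed, msk)
  logits <- drop(dense_fwd(eh, p$headW, p$headb))
  list(logits = logits, embed = embed,
       cache = list(x = x, conv = caches, acts = acts, gap = g,
                    head_mask = msk, head_in = eh))
}

bwd_cnn <- function(model, cache, dlogits, dembed_extra = NULL) {
  spec <- model$spec; p <- model$params
  grads <- list()
  dl <- matrix(dlogits, ncol = 1)
  dh <- dense_bwd(cache$head_in, p$headW, dl)
  grads$headW <- dh$dW; grads$headb <- dh$db
  dembed <- apply_mask(dh$dx, cache$head_mask)
  if (!is.null(dembed_extra)) dembed <- dembed + dembed_extra
  dhid <- gap_bwd(cache$gap, dembed)
  for (i in rev(seq_along(spec$conv_channels))) {
    cv <- cache$conv[[i]]
    if (spec$extra_dropout) dhid <- apply_mask(dhid, cv$extra_mask)
    dpre <- dhid * leaky_relu_grad(cache$acts[[i]])
    bw <- conv1d_bwd(cv, p[[paste0("convW", i)]], dpre)
    grads[[paste0("convW", i)]] <- bw$dW
    grads[[paste0("convb", i)]] <- bw$db
    dhid <- bw$dx
  }
  grads
}

# ---- LSTM -------------------------------------------------------------------

init_lstm <- function(spec, C) {
  H <- spec$hidden
  params <- list()
  in_dim <- C
  for (l in seq_len(spec$lstm_layers)) {
    params[[paste0("Wx", l)]] <- he_init(in_dim, 4 * H, in_dim)
    params[[paste0("Wh", l)]] <- he_init(H, 4 * H, H)
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1   # forget-gate bias init
    params[[paste0("b", l)]] <- b
    in_dim <- H
  }
  params$headW <- he_init(H, 1L, H)
  params$headb <- 0
  list(params = params,
       embed_params = grep("^(Wx|Wh|b)[0-9]+$", names(params), value = TRUE),
       embed_dim = H)
}

lstm_layer_fwd <- function(x, Wx, Wh, b) {
  n <- dim(x)[1]; T_len <- dim(x)[2]; H <- ncol(Wh) / 4
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps <- vector("list", T_len)
  out <- array(0, c(n, T_len, H))
  for (t in seq_len(T_len)) {
    xt <- matrix(x[, t, ], n)
    z <- xt %*% Wx + h %*% Wh
    z <- sweep(z, 2, b, `+`)
    i_g <- sigmoid(z[, 1:H, drop = FALSE])
    f_g <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g_g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o_g <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i_g, f = f_g,
                       g = g_g, o = o_g, c = c_new, tc = tc)
    h <- h_new; cc <- c_new
    out[, t, ] <- h
  }
  list(out = out, steps = steps, H = H)
}

lstm_layer_bwd <- function(cache, Wx, Wh, dout, dh_last = NULL) {
  T_len <- length(cache$steps); H <- cache$H
  n <- nrow(cache$steps[[1]]$h_prev)
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- rep(0, 4 * H)
  dh_next <- if (is.null(dh_last)) matrix(0, n, H) else dh_last
  dc_next <- matrix(0, n, H)
  dx <- array(0, c(n, T_len, nrow(Wx)))
  for (t in rev(seq_len(T_len))) {
    st <- cache$steps[[t]]
    dh <- dh_next + matrix(dout[, t, ], n)
    do_g <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_g * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * st$f
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

fwd_lstm <- function(model, x, training = FALSE) {
  spec <- model$spec; p <- model$params
  layers <- list(); masks <- list()
  h <- x
  for (l in seq_len(spec$lstm_layers)) {
    lf <- lstm_layer_fwd(h, p[[paste0("Wx", l)]], p[[paste0("Wh", l)]],
                         p[[paste0("b", l)]])
    layers[[l]] <- lf
    h <- lf$out
    if (l < spec$lstm_layers) {
      msk <- dropout_mask(dim(h), spec$dropout, training)
      masks[[l]] <- msk %||% NA
      h <- apply_mask(h, msk)
    }
  }
  n <- dim(x)[1]; T_len <- dim(x)[2]
  embed <- matrix(h[, T_len, ], n)
  msk <- dropout_mask(dim(embed), spec$dropout, training)
  eh <- apply_mask(embed, msk)
  logits <- drop(dense_fwd(eh, p$headW, p$headb))
  list(logits = logits, embed = embed,
       cache = list(layers = layers, masks = masks, head_mask = msk,
                    head_in = eh, T_len = T_len))
}

bwd_lstm <- function(model, cache, dlogits, dembed_extra = NULL) {
  spec <- model$spec; p <- model$params
  grads <- list()
  dl <- matrix(dlogits, ncol = 1)
  dh <- dense_bwd(cache$head_in, p$headW, dl)
  grads$headW <- dh$dW; grads$headb <- dh$db
  dembed <- apply_mask(dh$dx, cache$head_mask)
  if (!is.null(dembed_extra)) dembed <- dembed + dembed_extra
  T_len <- cache$T_len
  n <- nrow(dembed)
  dout <- array(0, c(n, T_len, ncol(dembed)))
  dout[, T_len, ] <- dembed
  for (l in rev(seq_len(spec$lstm_layers))) {
    if (l < spec$lstm_layers) {
      msk <- cache$masks[[l]]
      if (!is.null(msk) && !identical(msk, NA)) dout <- dout * msk
    }
    bw <- lstm_layer_bwd(cache$layers[[l]], p[[paste0("Wx", l)]],
                         p[[paste0("Wh", l)]], dout)
    grads[[paste0("Wx", l)]] <- bw$dWx
    grads[[paste0("Wh", l)]] <- bw$dWh
    grads[[paste0("b", l)]] <- bw$db
    dout <- bw$dx
  }
  grads
}

# ---- InceptionTime ----------------------------------------------------------

inception_kernels <- c(3L, 5L, 7L)

init_inception <- function(spec, C) {
  f <- spec$filters; B <- spec$bottleneck
  params <- list()
  c_in <- C
  res_ch <- C   # channel width of the current residual source
  out_ch <- 4L * f
  for (m in seq_len(spec$depth)) {
    params[[paste0("botW", m)]] <- he_init(c_in, B, c_in)
    params[[paste0("botb", m)]] <- rep(0, B)
    for (j in seq_along(inception_kernels)) {
      k <- inception_kernels[j]
      params[[paste0("incW", m, "_", j)]] <- he_init(k * B, f, k * B)
      params[[paste0("incb", m, "_", j)]] <- rep(0, f)
    }
    params[[paste0("poolW", m)]] <- he_init(c_in, f, c_in)
    params[[paste0("poolb", m)]] <- rep(0, f)
    if (m %% 3 == 0) {
      params[[paste0("resW", m)]] <- he_init(res_ch, out_ch, res_ch)
      params[[paste0("resb", m)]] <- rep(0, out_ch)
      res_ch <- out_ch
    }
    c_in <- out_ch
  }
  params$headW <- he_init(out_ch, 1L, out_ch)
  params$headb <- 0
  list(params = params,
       embed_params = grep("^(bot|inc|pool|res)", names(params), value = TRUE),
       embed_dim = out_ch)
}

fwd_inception <- function(model, x, training = FALSE) {
  spec <- model$spec; p <- model$params
  mods <- list()
  h <- x
  res_src <- x
  for (m in seq_len(spec$depth)) {
    cm <- list(input = h)
    # 1x1 bottleneck (a dense map applied at every time step)
    bot <- conv1d_fwd(h, p[[paste0("botW", m)]], p[[paste0("botb", m)]], 1L)
    cm$bot <- bot
    branches <- list(); br_out <- list()
    for (j in seq_along(inception_kernels)) {
      cv <- conv1d_fwd(bot$out, p[[paste0("incW", m, "_", j)]],
                       p[[paste0("incb", m, "_", j)]], inception_kernels[j])
      branches[[j]] <- cv
      br_out[[j]] <- cv$out
    }
    mp <- maxpool1d_fwd(h, 3L)
    pv <- conv1d_fwd(mp$out, p[[paste0("poolW", m)]], p[[paste0("poolb", m)]], 1L)
    cm$branches <- branches; cm$mp <- mp; cm$pool <- pv
    pre <- abind_channels(c(br_out, list(pv$out)))
    if (m %% 3 == 0) {
      rs <- conv1d_fwd(res_src, p[[paste0("resW", m)]], p[[paste0("resb", m)]], 1L)
      cm$res <- rs
      pre <- pre + rs$out
    }
    cm$pre <- pre
    h <- leaky_relu(pre)
    if (spec$extra_dropout) {
      msk <- dropout_mask(dim(h), spec$dropout, training)
      cm$extra_mask <- msk
      h <- apply_mask(h, msk)
    }
    if (m %% 3 == 0) res_src <- h
    mods[[m]] <- cm
  }
  g <- gap_fwd(h)
  embed <- g$out
  msk <- dropout_mask(dim(embed), spec$dropout, training)
  eh <- apply_mask(embed, msk)
  logits <- drop(dense_fwd(eh, p$headW, p$headb))
  list(logits = logits, embed = embed,
       cache = list(mods = mods, gap = g, head_mask = msk, head_in = eh))
}

abind_channels <- function(lst) {
  d <- dim(lst[[1]])
  C_total <- sum(map_int(lst, ~ dim(.x)[3]))
  out <- array(0, c(d[1], d[2], C_total))
  at <- 0L
  for (a in lst) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}

bwd_inception <- function(model, cache, dlogits, dembed_extra = NULL) {
  spec <- model$spec; p <- model$params
  f <- spec$filters
  grads <- list()
  dl <- matrix(dlogits, ncol = 1)
  dh <- dense_bwd(cache$head_in, p$headW, dl)
  grads$headW <- dh$dW; grads$headb <- dh$db
  dembed <- apply_mask(dh$dx, cache$head_mask)
  if (!is.null(dembed_extra)) dembed <- dembed + dembed_extra
  dhid <- gap_bwd(cache$gap, dembed)

  # gradient flowing to each residual source (set when passing module 3k)
  dres_pending <- list()
  for (m in rev(seq_len(spec$depth))) {
    cm <- cache$mods[[m]]
    # residual shortcut gradient joins at the *output* of module m when some
    # later module 3k used this module's output as its residual source
    if (!is.null(dres_pending[[as.character(m)]])) {
      dhid <- dhid + dres_pending[[as.character(m)]]
      dres_pending[[as.character(m)]] <- NULL
    }
    if (spec$extra_dropout) dhid <- apply_mask(dhid, cm$extra_mask)
    dpre <- dhid * leaky_relu_grad(cm$pre)
    dinput <- array(0, dim(cm$input))

    if (m %% 3 == 0) {
      rs <- cm$res
      bwr <- conv1d_bwd(rs, p[[paste0("resW", m)]], dpre)
      grads[[paste0("resW", m)]] <- bwr$dW
      grads[[paste0("resb", m)]] <- bwr$db
      # route to the residual source: module (m-3)'s output, or the input
      src_mod <- m - 3L
      if (src_mod >= 1L) {
        key <- as.character(src_mod)
        dres_pending[[key]] <- (dres_pending[[key]] %||% 0) + bwr$dx
      } else {
        dres_pending[["0"]] <- (dres_pending[["0"]] %||% 0) + bwr$dx
      }
    }

    at <- 0L
    dbot_total <- NULL
    for (j in seq_along(inception_kernels)) {
      dsl <- dpre[, , at + seq_len(f), drop = FALSE]
      bw <- conv1d_bwd(cm$branches[[j]], p[[paste0("incW", m, "_", j)]], dsl)
      grads[[paste0("incW", m, "_", j)]] <- bw$dW
      grads[[paste0("incb", m, "_", j)]] <- bw$db
      dbot_total <- if (is.null(dbot_total)) bw$dx else dbot_total + bw$dx
      at <- at + f
    }
    dsl <- dpre[, , at + seq_len(f), drop = FALSE]
    bwp <- conv1d_bwd(cm$pool, p[[paste0("poolW", m)]], dsl)
    grads[[paste0("poolW", m)]] <- bwp$dW
    grads[[paste0("poolb", m)]] <- bwp$db
    dinput <- dinput + maxpool1d_bwd(cm$mp, bwp$dx)

    bwb <- conv1d_bwd(cm$bot, p[[paste0("botW", m)]], dbot_total)
    grads[[paste0("botW", m)]] <- bwb$dW
    grads[[paste0("botb", m)]] <- bwb$db
    dinput <- dinput + bwb$dx
    dhid <- dinput
  }
  # any residual gradient routed to the network input is discarded (input is
  # data, not a parameter)
  grads
}

# ---- unified forward/backward dispatch --------------------------------------

model_forward <- function(model, x, training = FALSE) {
  switch(model$spec$arch,
    cnn = fwd_cnn(model, x, training),
    lstm = fwd_lstm(model, x, training),
    inceptiontime = fwd_inception(model, x, training)
  )
}

model_backward <- function(model, cache, dlogits, dembed_extra = NULL) {
  switch(model$spec$arch,
    cnn = bwd_cnn(model, cache, dlogits, dembed_extra),
    lstm = bwd_lstm(model, cache, dlogits, dembed_extra),
    inceptiontime = bwd_inception(model, cache, dlogits, dembed_extra)
  )
}

#' Embeddings of a window batch
#'
#' Runs the embedding stage only (no dropout, no head).
#'
#' @param model A `sepshift_model`.
#' @param windows A `window_set` (or a plain `n x hours x channels` array).
#' @return Matrix `n x embed_dim`.
#' @export
embed_windows <- function(model, windows) {
  x <- if (inherits(windows, "window_set")) windows$x else windows
  model_forward(model, x, training = FALSE)$embed
}

#' Predicted sepsis scores
#'
#' Sigmoid of the model logits; deterministic and independent of batch
#' composition.
#'
#' @param model A trained `sepshift_model`.
#' @param windows A `window_set` (scaled as at training time) or array.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict_scores <- function(model, windows) {
  x <- if (inherits(windows, "window_set")) windows$x else windows
  if (dim(x)[3] != model$window_shape[2]) {
    abort("window channels do not match the model's input channels")
  }
  sigmoid(model_forward(model, x, training = FALSE)$logits)
}
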