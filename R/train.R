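#' Training configuration
#'
#' The per-architecture training protocol: batch size 32, binary
#' cross-entropy on logits with the positive class weighted by the training
#' negative/positive ratio, early stopping after five epochs without a new
#' best validation loss, and a reduce-on-plateau learning-rate schedule.
#' Architecture defaults:
#'
#' | arch | optimizer | lr | scheduler factor | min lr | max epochs |
#' |------|-----------|-----|------|--------|-----|
#' | cnn | SGD (momentum 0.85, weight decay 1e-4) | 0.01 | 0.9 | 1e-3 | 150 |
#' | lstm | AdamW | 0.001 | 0.85 | 1e-4 | 120 |
#' | inceptiontime | AdamW | 0.01 | 0.9 | 1e-3 | 60 |
#'
#' @param arch Architecture name (sets the defaults above).
#' @param batch_size Minibatch size (default 32).
#' @param lr,optimizer,momentum,weight_decay Optimizer settings.
#' @param sched_factor,sched_patience,min_lr Plateau scheduler settings.
#' @param max_epochs,patience Epoch cap and early-stopping patience.
#' @param seed Seed governing shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(arch = c("cnn", "lstm", "inceptiontime"),
                         batch_size = 32L,
                         lr = NULL, optimizer = NULL,
                         momentum = 0.85, weight_decay = 1e-4,
                         sched_factor = NULL, sched_patience = 5L,
                         min_lr = NULL, max_epochs = NULL, patience = 5L,
                         seed = 1L) {
  arch <- match.arg(arch)
  defaults <- switch(arch,
    cnn = list(lr = 0.01, optimizer = "sgd", sched_factor = 0.9,
               min_lr = 1e-3, max_epochs = 150L),
    lstm = list(lr = 0.001, optimizer = "adamw", sched_factor = 0.85,
                min_lr = 1e-4, max_epochs = 120L),
    inceptiontime = list(lr = 0.01, optimizer = "adamw", sched_factor = 0.9,
                         min_lr = 1e-3, max_epochs = 60L)
  )
  cfg <- list(
    arch = arch, batch_size = as.integer(batch_size),
    lr = lr %||% defaults$lr,
    optimizer = optimizer %||% defaults$optimizer,
    momentum = momentum, weight_decay = weight_decay,
    sched_factor = sched_factor %||% defaults$sched_factor,
    sched_patience = as.integer(sched_patience),
    min_lr = min_lr %||% defaults$min_lr,
    max_epochs = as.integer(max_epochs %||% defaults$max_epochs),
    patience = as.integer(patience),
    seed = as.integer(seed)
  )
  if (cfg$min_lr > cfg$lr) abort("min_lr must not exceed the initial lr")
  if (cfg$patience < 1) abort("patience must be >= 1")
  structure(cfg, class = "train_config")
}

pos_weight_of <- function(labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("training set must contain both classes (positive-class weight undefined)")
  }
  n_neg / n_pos
}

eval_loss <- function(model, windows, pos_weight) {
  fw <- model_forward(model, windows$x, training = FALSE)
  bce_logits(fw$logits, windows$label, pos_weight)$loss
}

#' Train a model
#'
#' Minibatch training with the protocol of [train_config()]: weighted BCE on
#' logits, reduce-on-plateau scheduling, early stopping on validation loss,
#' and retention of the best-epoch parameters. Fully reproducible given the
#' config seed (shuffling and dropout both derive from it).
#'
#' @param model An untrained (or pre-trained, for transfer) `sepshift_model`.
#' @param train,val Scaled `window_set`s; `val` non-empty.
#' @param config A [train_config()].
#' @param frozen Names of parameters to keep fixed (e.g. the embedding
#'   parameters for fine-tuning).
#' @return The model with `history` (per-epoch train/val loss and lr),
#'   `best_epoch`, `best_val_loss`, and best-epoch parameters installed.
#' @export
train_model <- function(model, train, val, config, frozen = character()) {
  # force the model before seeding so an inlined build_model() call cannot
  # interleave its initialization draws with the training stream
  stopifnot(inherits(model, "sepshift_model"), inherits(config, "train_config"))
  if (n_windows(val) == 0) abort("validation windows must be non-empty")
  pw <- pos_weight_of(train$label)
  set.seed(config$seed)
  opt <- opt_init(model$params, config$optimizer)
  sched <- new_plateau(config$lr)
  best <- list(val = Inf, epoch = 0L, params = model$params)
  history <- list()
  n <- n_windows(train)
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- train$x[idx, , , drop = FALSE]
      yb <- train$label[idx]
      fw <- model_forward(model, xb, training = TRUE)
      lo <- bce_logits(fw$logits, yb, pw)
      grads <- model_backward(model, fw$cache, lo$dz)
      st <- opt_step(model$params, grads, opt, sched$lr, frozen = frozen,
                     momentum = config$momentum,
                     weight_decay = config$weight_decay)
      model$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + lo$loss * length(idx)
    }
    val_loss <- eval_loss(model, val, pw)
    history[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss / n,
                               val_loss = val_loss, lr = sched$lr)
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, epoch = epoch, params = model$params)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    sched <- plateau_step(sched, val_loss, config$sched_factor,
                          config$sched_patience, config$min_lr)
    if (stale >= config$patience) break
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$val
  model$history <- list_rbind(history)
  model$pos_weight <- pw
  model$train_config <- config
  model
}

#' Jointly train with a domain-alignment loss
#'
#' Supervised domain adaptation: per step, one batch from each domain (the
#' smaller domain is cycled to match the larger within each epoch, so an
#' epoch is one pass over the larger domain), with total loss
#' `BCE(source) + BCE(target) + lambda * DA(embed_s, embed_t)` where the
#' alignment term is multi-kernel MMD or CORAL on the embedding stage.
#' Model selection and early stopping use the target validation loss.
#'
#' @param model An untrained `sepshift_model`.
#' @param source_train,target_train Scaled labeled `window_set`s; both
#'   non-empty.
#' @param target_val Scaled target validation `window_set`.
#' @param da A [da_config()].
#' @param config A [train_config()].
#' @return A trained `sepshift_model` (as [train_model()]).
#' @export
train_da <- function(model, source_train, target_train, target_val,
                     da, config) {
  stopifnot(inherits(model, "sepshift_model"), inherits(config, "train_config"),
            inherits(da, "da_config"))
  if (n_windows(source_train) == 0 || n_windows(target_train) == 0) {
    abort("both domains must be non-empty for domain adaptation")
  }
  pw_s <- pos_weight_of(source_train$label)
  pw_t <- pos_weight_of(target_train$label)
  set.seed(config$seed)
  opt <- opt_init(model$params, config$optimizer)
  sched <- new_plateau(config$lr)
  best <- list(val = Inf, epoch = 0L, params = model$params)
  history <- list()
  n_s <- n_windows(source_train); n_t <- n_windows(target_train)
  n_big <- max(n_s, n_t)
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord_s <- sample.int(n_s)
    ord_t <- sample.int(n_t)
    # cycle the smaller domain to the length of the larger
    if (n_s < n_big) ord_s <- rep_len(ord_s, n_big)
    if (n_t < n_big) ord_t <- rep_len(ord_t, n_big)
    starts <- seq(1L, n_big, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      take <- s:min(s + config$batch_size - 1L, n_big)
      is_ <- ord_s[take]; it_ <- ord_t[take]
      xs <- source_train$x[is_, , , drop = FALSE]
      ys <- source_train$label[is_]
      xt <- target_train$x[it_, , , drop = FALSE]
      yt <- target_train$label[it_]

      fs <- model_forward(model, xs, training = TRUE)
      ft <- model_forward(model, xt, training = TRUE)
      ls <- bce_logits(fs$logits, ys, pw_s)
      lt <- bce_logits(ft$logits, yt, pw_t)
      dal <- da_loss_grad(fs$embed, ft$embed, da)
      g_s <- model_backward(model, fs$cache, ls$dz,
                            dembed_extra = da$lambda * dal$d_s)
      g_t <- model_backward(model, ft$cache, lt$dz,
                            dembed_extra = da$lambda * dal$d_t)
      grads <- map2(g_s[names(model$params)], g_t[names(model$params)],
                    function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b)
      names(grads) <- names(model$params)
      st <- opt_step(model$params, grads, opt, sched$lr,
                     momentum = config$momentum,
                     weight_decay = config$weight_decay)
      model$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + (ls$loss + lt$loss + da$lambda * dal$loss) * length(take)
    }
    val_loss <- eval_loss(model, target_val, pw_t)
    history[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss / n_big,
                               val_loss = val_loss, lr = sched$lr)
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, epoch = epoch, params = model$params)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    sched <- plateau_step(sched, val_loss, config$sched_factor,
                          config$sched_patience, config$min_lr)
    if (stale >= config$patience) break
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$val
  model$history <- list_rbind(history)
  model$pos_weight <- pw_t
  model$train_config <- config
  model
}

#' @export
tidy.sepshift_model <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history; train it first")
  }
  x$history
}

#' @export
glance.sepshift_model <- function(x, ...) {
  tibble(
    arch = x$spec$arch,
    n_parameters = sum(map_int(x$params, ~ length(.x))),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = x$best_val_loss %||% NA_real_
  )
}
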