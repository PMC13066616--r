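#' Multi-kernel MMD parameters
#'
#' Knobs of the Gaussian-RBF maximum mean discrepancy: `kernel_num` kernels
#' with bandwidths on a geometric ladder centered at `fix_sigma`,
#' `bw_i = fix_sigma * kernel_mul^(i - floor(kernel_num / 2))` for
#' `i = 0 .. kernel_num - 1`. Defaults `kernel_num = 5`, `kernel_mul = 2`,
#' `fix_sigma = 1`; the CNN uses `kernel_mul = 5`.
#'
#' @param kernel_num Number of kernels (>= 1).
#' @param kernel_mul Bandwidth multiplier (> 1).
#' @param fix_sigma Central bandwidth (> 0).
#' @return An object of class `mmd_params`.
#' @export
mmd_params <- function(kernel_num = 5L, kernel_mul = 2.0, fix_sigma = 1.0) {
  if (kernel_num < 1) abort("kernel_num must be >= 1")
  if (kernel_mul <= 1) abort("kernel_mul must be > 1")
  if (fix_sigma <= 0) abort("fix_sigma must be > 0")
  structure(list(kernel_num = as.integer(kernel_num),
                 kernel_mul = kernel_mul, fix_sigma = fix_sigma),
            class = "mmd_params")
}

mmd_bandwidths <- function(params) {
  i <- seq_len(params$kernel_num) - 1L
  params$fix_sigma * params$kernel_mul^(i - params$kernel_num %/% 2L)
}

#' Domain-adaptation configuration
#'
#' Alignment method and adaptation weight for joint training. Default
#' weights follow the per-architecture settings: MMD `lambda` 1 for CNN and
#' LSTM and 10 for InceptionTime; CORAL `lambda` 1000 for CNN and 10000 for
#' LSTM and InceptionTime. The CNN's MMD uses `kernel_mul = 5`.
#'
#' @param method `"mmd"` or `"coral"`.
#' @param arch Architecture the defaults are resolved for.
#' @param lambda Adaptation weight (> 0); default per method and arch.
#' @param mmd MMD kernel parameters; default per arch.
#' @return An object of class `da_config`.
#' @export
da_config <- function(method = c("mmd", "coral"),
                      arch = c("cnn", "lstm", "inceptiontime"),
                      lambda = NULL, mmd = NULL) {
  method <- match.arg(method)
  arch <- match.arg(arch)
  if (is.null(lambda)) {
    lambda <- if (method == "mmd") {
      switch(arch, cnn = 1, lstm = 1, inceptiontime = 10)
    } else {
      switch(arch, cnn = 1000, lstm = 10000, inceptiontime = 10000)
    }
  }
  if (lambda <= 0) abort("lambda must be > 0")
  if (is.null(mmd)) {
    mmd <- mmd_params(kernel_mul = if (arch == "cnn") 5.0 else 2.0)
  }
  structure(list(method = method, arch = arch, lambda = lambda, mmd = mmd),
            class = "da_config")
}

#' Multi-kernel maximum mean discrepancy
#'
#' Biased (V-statistic) estimator summed over the bandwidth ladder:
#' `sum_k [ mean K_ss + mean K_tt - 2 mean K_st ]` with Gaussian RBF kernels
#' `k(x, y) = exp(-||x - y||^2 / bw_k)`. Zero when the two batches are
#' identical. Set `unbiased = TRUE` for the U-statistic variant (diagonal
#' terms of the within-domain blocks removed).
#'
#' @param embed_s,embed_t Embedding matrices (rows = samples) of equal
#'   dimension.
#' @param params An [mmd_params()].
#' @param unbiased Use the U-statistic estimator (default `FALSE`).
#' @return Non-negative scalar.
#' @export
mmd_loss <- function(embed_s, embed_t, params = mmd_params(),
                     unbiased = FALSE) {
  embed_s <- as.matrix(embed_s); embed_t <- as.matrix(embed_t)
  if (ncol(embed_s) != ncol(embed_t)) {
    abort("source and target embeddings must have equal dimension")
  }
  d2 <- function(a, b) {
    an <- rowSums(a^2); bn <- rowSums(b^2)
    pmax(outer(an, bn, `+`) - 2 * tcrossprod(a, b), 0)
  }
  Dss <- d2(embed_s, embed_s); Dtt <- d2(embed_t, embed_t)
  Dst <- d2(embed_s, embed_t)
  ns <- nrow(embed_s); nt <- nrow(embed_t)
  total <- 0
  for (bw in mmd_bandwidths(params)) {
    Kss <- exp(-Dss / bw); Ktt <- exp(-Dtt / bw); Kst <- exp(-Dst / bw)
    if (unbiased && ns > 1 && nt > 1) {
      mss <- (sum(Kss) - ns) / (ns * (ns - 1))
      mtt <- (sum(Ktt) - nt) / (nt * (nt - 1))
    } else {
      mss <- mean(Kss); mtt <- mean(Ktt)
    }
    total <- total + mss + mtt - 2 * mean(Kst)
  }
  total
}

# MMD value plus gradients with respect to both embedding batches
# (biased estimator; used inside the DA training loop).
mmd_loss_grad <- function(embed_s, embed_t, params) {
  s <- as.matrix(embed_s); t_ <- as.matrix(embed_t)
  ns <- nrow(s); nt <- nrow(t_)
  d2 <- function(a, b) {
    an <- rowSums(a^2); bn <- rowSums(b^2)
    pmax(outer(an, bn, `+`) - 2 * tcrossprod(a, b), 0)
  }
  Dss <- d2(s, s); Dtt <- d2(t_, t_); Dst <- d2(s, t_)
  loss <- 0
  dS <- matrix(0, ns, ncol(s)); dT <- matrix(0, nt, ncol(t_))
  for (bw in mmd_bandwidths(params)) {
    Kss <- exp(-Dss / bw); Ktt <- exp(-Dtt / bw); Kst <- exp(-Dst / bw)
    loss <- loss + mean(Kss) + mean(Ktt) - 2 * mean(Kst)
    # d mean(Kss) / dS_i = (-4 / (bw ns^2)) * (rowSums(Kss) * S_i - Kss S)
    dS <- dS + (-4 / (bw * ns^2)) * (rowSums(Kss) * s - Kss %*% s)
    dT <- dT + (-4 / (bw * nt^2)) * (rowSums(Ktt) * t_ - Ktt %*% t_)
    # cross term: d(-2 mean Kst)/dS_i = (4 / (bw ns nt)) (rowSums(Kst) S_i - Kst T)
    dS <- dS + (4 / (bw * ns * nt)) * (rowSums(Kst) * s - Kst %*% t_)
    dT <- dT + (4 / (bw * ns * nt)) * (colSums(Kst) * t_ - t(Kst) %*% s)
  }
  list(loss = loss, d_s = dS, d_t = dT)
}

#' Correlation alignment (CORAL) loss
#'
#' Squared Frobenius distance between the sample covariance matrices of the
#' two embedding batches, normalized by `4 d^2`:
#' `||C_s - C_t||_F^2 / (4 d^2)`. Translation-invariant and zero for
#' identical batches.
#'
#' @param embed_s,embed_t Embedding matrices with at least two rows each and
#'   equal dimension `d`.
#' @return Non-negative scalar.
#' @export
coral_loss <- function(embed_s, embed_t) {
  s <- as.matrix(embed_s); t_ <- as.matrix(embed_t)
  if (nrow(s) < 2 || nrow(t_) < 2) {
    abort("coral_loss needs at least 2 rows per batch (covariance undefined)")
  }
  if (ncol(s) != ncol(t_)) abort("embeddings must have equal dimension")
  d <- ncol(s)
  D <- stats::cov(s) - stats::cov(t_)
  sum(D^2) / (4 * d^2)
}

coral_loss_grad <- function(embed_s, embed_t) {
  s <- as.matrix(embed_s); t_ <- as.matrix(embed_t)
  d <- ncol(s)
  Zs <- scale(s, center = TRUE, scale = FALSE)
  Zt <- scale(t_, center = TRUE, scale = FALSE)
  Cs <- crossprod(Zs) / (nrow(s) - 1)
  Ct <- crossprod(Zt) / (nrow(t_) - 1)
  D <- Cs - Ct
  loss <- sum(D^2) / (4 * d^2)
  # dL/dZ = Z (G + G^T) / (n - 1) with G = dL/dC = D / (2 d^2), G symmetric
  gs <- Zs %*% D / ((nrow(s) - 1) * d^2)
  gt <- -Zt %*% D / ((nrow(t_) - 1) * d^2)
  # backprop through centering
  gs <- sweep(gs, 2, colMeans(gs))
  gt <- sweep(gt, 2, colMeans(gt))
  list(loss = loss, d_s = gs, d_t = gt)
}

da_loss_grad <- function(embed_s, embed_t, da) {
  if (da$method == "mmd") mmd_loss_grad(embed_s, embed_t, da$mmd)
  else coral_loss_grad(embed_s, embed_t)
}

# ---- strategy runners -------------------------------------------------------

strategy_row <- function(strategy, arch, source_id, target_id, fraction,
                         metrics, seed, config, data_digest) {
  tibble(
    strategy = strategy, arch = arch,
    source = source_id, target = target_id,
    target_fraction = fraction,
    auroc = metrics$auroc, auprc = metrics$auprc,
    nauprc = metrics$nauprc, recall = metrics$recall,
    seed = seed,
    config_hash = rlang::hash(config),
    data_digest = data_digest
  )
}

windows_digest <- function(ws) {
  rlang::hash(list(ws$provenance, dim(ws$x)))
}

new_strategy_run <- function(result, model) {
  structure(list(result = result, model = model), class = "strategy_run")
}

#' @export
print.strategy_run <- function(x, ...) {
  print(x$result)
  invisible(x)
}

#' @export
tidy.strategy_run <- function(x, ...) x$result

#' Evaluate a source model on the target test set (generalization)
#'
#' Direct deployment: no parameter update. The target test windows must be
#' scaled with the normalization the source model was trained under.
#'
#' @param source_model A trained `sepshift_model` (100% source training
#'   data).
#' @param target_test Scaled target test `window_set`.
#' @param source_id,target_id Site labels for bookkeeping.
#' @return A `strategy_run` (result row + the unchanged model).
#' @export
run_generalization <- function(source_model, target_test,
                               source_id = "source", target_id = "target") {
  if (!isTRUE(target_test$scaled)) {
    abort("target_test must be scaled (apply the source scaler) before evaluation")
  }
  scores <- predict_scores(source_model, target_test)
  m <- compute_metrics(scores, target_test$label)
  res <- strategy_row("generalization", source_model$spec$arch,
                      source_id, target_id, NA_real_, m,
                      source_model$train_config$seed %||% NA_integer_,
                      list(spec = source_model$spec), windows_digest(target_test))
  new_strategy_run(res, source_model)
}

#' Train on target data only
#'
#' Fresh initialization, standard protocol, evaluated on the target test
#' set.
#'
#' @param spec A [model_spec()].
#' @param train,val,test Scaled target `window_set`s (train = the target
#'   subset; test = full target test split).
#' @param config A [train_config()].
#' @param fraction Target-data fraction used (bookkeeping).
#' @param source_id,target_id Site labels.
#' @return A `strategy_run`.
#' @export
run_target_training <- function(spec, train, val, test, config,
                                fraction = 1.0,
                                source_id = "source", target_id = "target") {
  if (n_windows(train) == 0) abort("target training subset is empty")
  model <- build_model(spec, dim(train$x)[2:3], seed = config$seed)
  model <- train_model(model, train, val, config)
  scores <- predict_scores(model, test)
  m <- compute_metrics(scores, test$label)
  res <- strategy_row("target", spec$arch, source_id, target_id, fraction, m,
                      config$seed, list(spec = spec, config = unclass(config)),
                      windows_digest(test))
  new_strategy_run(res, model)
}

#' Fusion training on pooled source + target data
#'
#' Trains from scratch on the union of the source training windows and the
#' target subset (an empty target subset reduces exactly to source
#' training). The caller provides windows on a common normalization — the
#' scaler is refit on the pooled training data upstream.
#'
#' @param spec A [model_spec()].
#' @param source_train Scaled source training `window_set`.
#' @param target_train Scaled target subset `window_set` (may be empty).
#' @param val,test Scaled validation (target) and target test sets.
#' @inheritParams run_target_training
#' @return A `strategy_run`.
#' @export
run_fusion <- function(spec, source_train, target_train, val, test, config,
                       fraction = 1.0,
                       source_id = "source", target_id = "target") {
  pooled <- if (n_windows(target_train) == 0) source_train
            else bind_windows(source_train, target_train)
  model <- build_model(spec, dim(pooled$x)[2:3], seed = config$seed)
  model <- train_model(model, pooled, val, config)
  scores <- predict_scores(model, test)
  m <- compute_metrics(scores, test$label)
  res <- strategy_row("fusion", spec$arch, source_id, target_id, fraction, m,
                      config$seed, list(spec = spec, config = unclass(config)),
                      windows_digest(test))
  new_strategy_run(res, model)
}

#' Fine-tune configuration overrides
#'
#' Fine-tuning keeps the protocol unchanged except for the plateau
#' scheduler's factor: 0.75 for CNN and InceptionTime, 0.7 for LSTM.
#'
#' @param arch Architecture.
#' @param base Base [train_config()] to override.
#' @return A `train_config`.
#' @export
finetune_config <- function(arch, base = train_config(arch)) {
  base$sched_factor <- if (arch == "lstm") 0.7 else 0.75
  base
}

#' Retraining overrides
#'
#' Full retraining reduces the learning rate, divides the scheduler factor
#' by 10, and strengthens dropout: CNN lr 0.001, dropout 0.5 to 0.6 plus an
#' added dropout layer; LSTM lr 1e-4, dropout uniformly 0.6; InceptionTime
#' lr 1e-4, dropout 0.3 to 0.7 with dropout after every module.
#'
#' @param arch Architecture.
#' @param base Base [train_config()] to override.
#' @return List with `config` (a `train_config`) and `spec_overrides`
#'   (`dropout`, `extra_dropout`) to apply to the model spec.
#' @export
retrain_config <- function(arch, base = train_config(arch)) {
  base$sched_factor <- base$sched_factor / 10
  base$lr <- switch(arch, cnn = 0.001, lstm = 1e-4, inceptiontime = 1e-4)
  base$min_lr <- min(base$min_lr, base$lr)
  dropout <- switch(arch, cnn = 0.6, lstm = 0.6, inceptiontime = 0.7)
  list(config = base,
       spec_overrides = list(dropout = dropout, extra_dropout = TRUE))
}

#' Fine-tune a pre-trained model on target data
#'
#' Updates only the classification head; every embedding-stage parameter is
#' frozen (bit-identical before and after).
#'
#' @param source_model A trained `sepshift_model`.
#' @param train,val,test Scaled target `window_set`s (on the source model's
#'   normalization).
#' @param config Optional [train_config()]; defaults to
#'   [finetune_config()] for the model's architecture.
#' @inheritParams run_target_training
#' @return A `strategy_run`.
#' @export
run_finetune <- function(source_model, train, val, test, config = NULL,
                         fraction = 1.0,
                         source_id = "source", target_id = "target") {
  arch <- source_model$spec$arch
  if (is.null(config)) config <- finetune_config(arch)
  model <- train_model(source_model, train, val, config,
                       frozen = source_model$embed_params)
  scores <- predict_scores(model, test)
  m <- compute_metrics(scores, test$label)
  res <- strategy_row("finetune", arch, source_id, target_id, fraction, m,
                      config$seed, list(spec = model$spec, config = unclass(config)),
                      windows_digest(test))
  new_strategy_run(res, model)
}

#' Retrain a pre-trained model on target data
#'
#' All parameters trainable, initialized from the source model, with the
#' stated learning-rate, scheduler, and dropout overrides.
#'
#' @inheritParams run_finetune
#' @param config Optional `train_config`; defaults to
#'   `retrain_config(arch)$config`.
#' @return A `strategy_run`.
#' @export
run_retrain <- function(source_model, train, val, test, config = NULL,
                        fraction = 1.0,
                        source_id = "source", target_id = "target") {
  arch <- source_model$spec$arch
  rc <- retrain_config(arch)
  if (is.null(config)) config <- rc$config
  model <- source_model
  model$spec$dropout <- rc$spec_overrides$dropout
  model$spec$extra_dropout <- rc$spec_overrides$extra_dropout
  model <- train_model(model, train, val, config)
  scores <- predict_scores(model, test)
  m <- compute_metrics(scores, test$label)
  res <- strategy_row("retrain", arch, source_id, target_id, fraction, m,
                      config$seed, list(spec = model$spec, config = unclass(config)),
                      windows_digest(test))
  new_strategy_run(res, model)
}

#' Supervised domain adaptation
#'
#' Joint training on labeled source and target data with an MMD or CORAL
#' alignment penalty on the embeddings (see [train_da()]).
#'
#' @param spec A [model_spec()].
#' @param source_train,target_train,target_val,target_test Scaled
#'   `window_set`s on a common normalization.
#' @param da A [da_config()].
#' @param config A [train_config()].
#' @inheritParams run_target_training
#' @return A `strategy_run`.
#' @export
run_da <- function(spec, source_train, target_train, target_val, target_test,
                   da = da_config("mmd", spec$arch), config = NULL,
                   fraction = 1.0,
                   source_id = "source", target_id = "target") {
  if (is.null(config)) config <- train_config(spec$arch)
  model <- build_model(spec, dim(source_train$x)[2:3], seed = config$seed)
  model <- train_da(model, source_train, target_train, target_val, da, config)
  scores <- predict_scores(model, target_test)
  m <- compute_metrics(scores, target_test$label)
  res <- strategy_row(paste0("da_", da$method), spec$arch, source_id,
                      target_id, fraction, m,
                      config$seed,
                      list(spec = spec, config = unclass(config), da = unclass(da)),
                      windows_digest(target_test))
  new_strategy_run(res, model)
}
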