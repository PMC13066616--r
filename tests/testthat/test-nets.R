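# finite-difference gradient checks guard the hand-derived backprop of every
# architecture

num_grad_check <- function(spec, n = 4L, T_len = 6L, C = 3L, picks = 4L) {
  set.seed(42)
  x <- array(rnorm(n * T_len * C), c(n, T_len, C))
  y <- rep(c(TRUE, FALSE), length.out = n)
  m <- build_model(spec, c(T_len, C), seed = 7L)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    fw <- sepshift:::model_forward(m2, x, training = FALSE)
    sepshift:::bce_logits(fw$logits, y, pos_weight = 1.5)$loss
  }
  fw <- sepshift:::model_forward(m, x, training = FALSE)
  lo <- sepshift:::bce_logits(fw$logits, y, pos_weight = 1.5)
  gr <- sepshift:::model_backward(m, fw$cache, lo$dz)
  eps <- 1e-5
  worst <- 0
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(picks, length(m$params[[nm]])))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- gr[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  worst
}

test_that("backpropagation matches finite differences for all architectures", {
  expect_lt(num_grad_check(model_spec("cnn", conv_channels = c(3L, 4L, 4L))), 1e-4)
  expect_lt(num_grad_check(model_spec("lstm", hidden = 5L)), 1e-4)
  expect_lt(num_grad_check(model_spec("inceptiontime", depth = 6L, filters = 3L,
                                      bottleneck = 2L)), 1e-4)
})

test_that("models expose an embedding/head split that composes to the forward pass", {
  for (spec in list(model_spec("cnn", conv_channels = c(4L, 4L, 4L)),
                    model_spec("lstm", hidden = 6L),
                    model_spec("inceptiontime", depth = 3L, filters = 2L,
                               bottleneck = 2L))) {
    m <- build_model(spec, c(6L, 5L), seed = 3L)
    x <- array(rnorm(7 * 6 * 5), c(7, 6, 5))
    e <- embed_windows(m, x)
    expect_equal(nrow(e), 7L)
    expect_equal(ncol(e), m$embed_dim)
    logits_direct <- sepshift:::model_forward(m, x)$logits
    logits_head <- drop(sepshift:::dense_fwd(e, m$params$headW, m$params$headb))
    expect_equal(logits_direct, logits_head)
    expect_true(all(m$embed_params %in% names(m$params)))
  }
})

test_that("the default InceptionTime stacks 12 serially composed modules", {
  spec <- model_spec("inceptiontime")
  expect_equal(spec$depth, 12L)
  m <- build_model(spec, c(6L, 4L), seed = 1L)
  expect_equal(sum(grepl("^botW", names(m$params))), 12L)
  expect_equal(sum(grepl("^resW", names(m$params))), 4L)  # shortcut every 3rd
})

test_that("initialization and training are deterministic in the seed", {
  spec <- model_spec("cnn", conv_channels = c(4L, 4L, 4L))
  a <- build_model(spec, c(6L, 4L), seed = 5L)
  b <- build_model(spec, c(6L, 4L), seed = 5L)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, build_model(spec, c(6L, 4L), seed = 6L)$params))

  set.seed(1)
  x <- array(rnorm(60 * 6 * 4), c(60, 6, 4))
  y <- x[, 6, 1] > 0
  ws <- sepshift:::new_window_set(x, y, tibble::tibble(stay_id = 1:60, end_hour = 5L),
                                  paste0("c", 1:4))
  tc <- train_config("cnn", max_epochs = 3L, seed = 9L)
  m1 <- train_model(build_model(spec, c(6L, 4L), seed = 5L), ws, ws, tc)
  m2 <- train_model(build_model(spec, c(6L, 4L), seed = 5L), ws, ws, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("training drives AUROC to 1 on linearly separable windows", {
  set.seed(7)
  n <- 240L
  x <- array(rnorm(n * 6 * 2), c(n, 6, 2))
  y <- rowMeans(x[, , 1]) > 0          # separable on channel-1 mean
  x[, , 1] <- x[, , 1] + ifelse(y, 1.5, -1.5)
  ws <- sepshift:::new_window_set(x, y, tibble::tibble(stay_id = seq_len(n),
                                                       end_hour = 5L),
                                  c("a", "b"))
  for (spec in list(model_spec("cnn", conv_channels = c(4L, 8L, 8L)),
                    model_spec("lstm", hidden = 8L),
                    model_spec("inceptiontime", depth = 2L, filters = 3L,
                               bottleneck = 2L))) {
    tc <- train_config(spec$arch, max_epochs = 20L, seed = 2L)
    m <- train_model(build_model(spec, c(6L, 2L), seed = 2L), ws, ws, tc)
    auc <- compute_metrics(predict_scores(m, ws), ws$label)$auroc
    expect_gt(auc, 0.99)
  }
})

test_that("early stopping halts after patience epochs without improvement", {
  # lr = 0 freezes the model, so the validation loss never improves after
  # epoch 1: training must stop at epoch patience + 1 with best_epoch 1
  set.seed(3)
  x <- array(rnorm(40 * 6 * 2), c(40, 6, 2))
  ws <- sepshift:::new_window_set(x, rep(c(TRUE, FALSE), 20),
                                  tibble::tibble(stay_id = 1:40, end_hour = 5L),
                                  c("a", "b"))
  tc <- train_config("cnn", lr = 0, min_lr = 0, max_epochs = 50L, seed = 1L)
  m <- train_model(build_model(model_spec("cnn", conv_channels = c(2L, 2L, 2L)),
                               c(6L, 2L), seed = 1L), ws, ws, tc)
  expect_equal(nrow(m$history), 6L)
  expect_equal(m$best_epoch, 1L)
  expect_equal(m$best_val_loss, m$history$val_loss[1])
  expect_lte(m$best_val_loss, min(m$history$val_loss))

  # a one-epoch cap yields a one-row history
  tc1 <- train_config("cnn", max_epochs = 1L, seed = 1L)
  m1 <- train_model(build_model(model_spec("cnn", conv_channels = c(2L, 2L, 2L)),
                                c(6L, 2L), seed = 1L), ws, ws, tc1)
  expect_equal(nrow(m1$history), 1L)
})

test_that("the plateau scheduler decays on stagnation and honors the floor", {
  tr <- sepshift:::new_plateau(0.01)
  tr <- sepshift:::plateau_step(tr, 1.0, 0.5, patience = 5, min_lr = 1e-3)  # best
  for (i in 1:4) tr <- sepshift:::plateau_step(tr, 1.0, 0.5, patience = 5, min_lr = 1e-3)
  expect_equal(tr$lr, 0.01)                 # four stale epochs: not yet
  tr <- sepshift:::plateau_step(tr, 1.0, 0.5, patience = 5, min_lr = 1e-3)
  expect_equal(tr$lr, 0.005)                # decayed after 5 stale epochs
  for (i in 1:40) tr <- sepshift:::plateau_step(tr, 1.0, 0.5, patience = 1, min_lr = 1e-3)
  expect_equal(tr$lr, 1e-3)                 # exact floor, never below
  # improvement resets the stale counter
  tr2 <- sepshift:::new_plateau(0.01)
  for (i in 1:4) tr2 <- sepshift:::plateau_step(tr2, 1.0, 0.5, 5, 1e-3)
  tr2 <- sepshift:::plateau_step(tr2, 0.5, 0.5, 5, 1e-3)
  for (i in 1:4) tr2 <- sepshift:::plateau_step(tr2, 0.6, 0.5, 5, 1e-3)
  expect_equal(tr2$lr, 0.01)
})

test_that("scores are sigmoid logits, order-independent, and shape-checked", {
  spec <- model_spec("cnn", conv_channels = c(3L, 3L, 3L))
  m <- build_model(spec, c(6L, 2L), seed = 4L)
  m$params$headW[] <- 0; m$params$headb <- 0
  x <- array(rnorm(10 * 6 * 2), c(10, 6, 2))
  expect_equal(predict_scores(m, x), rep(0.5, 10))  # logit 0 -> 0.5

  m2 <- build_model(spec, c(6L, 2L), seed = 4L)
  s <- predict_scores(m2, x)
  perm <- sample(10)
  expect_equal(predict_scores(m2, x[perm, , , drop = FALSE]), s[perm])
  dup <- x[c(1, 1), , , drop = FALSE]
  sd_ <- predict_scores(m2, dup)
  expect_equal(sd_[1], sd_[2])

  bad <- array(0, c(3, 6, 5))
  expect_error(predict_scores(m2, bad), "channels")
})

test_that("training refuses a single-class training set", {
  x <- array(rnorm(10 * 6 * 2), c(10, 6, 2))
  ws <- sepshift:::new_window_set(x, rep(FALSE, 10),
                                  tibble::tibble(stay_id = 1:10, end_hour = 5L),
                                  c("a", "b"))
  tc <- train_config("cnn", max_epochs = 1L)
  expect_error(train_model(build_model(model_spec("cnn"), c(6L, 2L)), ws, ws, tc),
               "both classes")
})
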