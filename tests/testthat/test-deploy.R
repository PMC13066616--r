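test_that("MMD is zero at identity and matches the closed form on singletons", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(mmd_loss(X, X), 0)
  # the U-statistic variant only removes the diagonal bias of the
  # within-domain blocks; on identical batches it is small and negative
  expect_lt(mmd_loss(X, X, unbiased = TRUE), 0)

  # 1-d singletons s = {0}, t = {1} with defaults (5 kernels, mul 2, sigma 1):
  # each kernel contributes 2 (1 - exp(-1 / bw)), bw in {1/4, 1/2, 1, 2, 4}
  bws <- c(0.25, 0.5, 1, 2, 4)
  expected <- sum(2 * (1 - exp(-1 / bws)))
  expect_equal(mmd_loss(matrix(0), matrix(1)), expected)

  expect_error(mmd_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "dimension")
})

test_that("MMD grows with the offset between batches", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  vals <- purrr::map_dbl(c(0, 0.5, 1, 2), ~ mmd_loss(X, X + .x))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[1], 0)
})

test_that("CORAL matches its analytic values and invariances", {
  set.seed(3)
  X <- matrix(rnorm(50), 10, 5)
  expect_equal(coral_loss(X, X), 0)
  # translation invariance
  expect_equal(coral_loss(X, X + matrix(rep(c(3, -1, 2, 0, 7), each = 10), 10)), 0)
  # d = 1, variances 1 vs 2 -> (1 - 2)^2 / 4
  a <- as.matrix(scale(rnorm(200)))            # var exactly 1
  b <- sqrt(2) * as.matrix(scale(rnorm(200)))  # var exactly 2
  expect_equal(coral_loss(a, b), 0.25, tolerance = 1e-12)
  expect_error(coral_loss(X[1, , drop = FALSE], X), "2 rows")
})

test_that("CORAL is invariant under a common orthogonal rotation", {
  set.seed(4)
  for (i in 1:5) {
    X <- matrix(rnorm(80), 20, 4)
    Y <- matrix(rnorm(60, sd = 1.3), 15, 4)
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    expect_equal(coral_loss(X %*% Q, Y %*% Q), coral_loss(X, Y),
                 tolerance = 1e-10)
  }
})

test_that("property: both alignment losses vanish on identical batches", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:20, 1); d <- sample(1:6, 1)
    X <- matrix(rnorm(n * d), n, d)
    expect_equal(mmd_loss(X, X), 0)
    if (n >= 2) expect_equal(coral_loss(X, X), 0)
  }
})

test_that("da_config resolves the per-architecture defaults", {
  expect_equal(da_config("mmd", "cnn")$lambda, 1)
  expect_equal(da_config("mmd", "inceptiontime")$lambda, 10)
  expect_equal(da_config("coral", "cnn")$lambda, 1000)
  expect_equal(da_config("coral", "lstm")$lambda, 10000)
  expect_equal(da_config("mmd", "cnn")$mmd$kernel_mul, 5.0)
  expect_equal(da_config("mmd", "lstm")$mmd$kernel_mul, 2.0)
  expect_equal(mmd_params()$kernel_num, 5L)
  expect_equal(mmd_params()$fix_sigma, 1.0)
  expect_error(mmd_params(kernel_mul = 1), "kernel_mul")
})

test_that("with a zero adaptation weight the joint loss is the two BCE terms", {
  spec <- model_spec("cnn", conv_channels = c(3L, 3L, 3L))
  m <- build_model(spec, c(6L, 2L), seed = 2L)
  xs <- array(rnorm(8 * 6 * 2), c(8, 6, 2)); ys <- rep(c(TRUE, FALSE), 4)
  xt <- array(rnorm(8 * 6 * 2), c(8, 6, 2)); yt <- rep(c(FALSE, TRUE), 4)
  fs <- sepshift:::model_forward(m, xs); ft <- sepshift:::model_forward(m, xt)
  ls <- sepshift:::bce_logits(fs$logits, ys); lt <- sepshift:::bce_logits(ft$logits, yt)
  da <- da_config("mmd", "cnn")
  dal <- sepshift:::da_loss_grad(fs$embed, ft$embed, da)
  total0 <- ls$loss + lt$loss + 0 * dal$loss
  expect_equal(total0, ls$loss + lt$loss)
  # and the zero-weighted embedding gradient changes nothing
  g0 <- sepshift:::model_backward(m, fs$cache, ls$dz, dembed_extra = 0 * dal$d_s)
  g_plain <- sepshift:::model_backward(m, fs$cache, ls$dz)
  expect_equal(g0, g_plain)
  # identical batches contribute no alignment term
  expect_equal(sepshift:::da_loss_grad(fs$embed, fs$embed, da)$loss, 0)
})

test_that("fine-tuning freezes the embedding stage bit-exactly", {
  prep <- fx_prep(seed = 3L, n = 300L)
  sc <- prep$scaler
  tr <- apply_scaler(prep$windows$train, sc)
  va <- apply_scaler(prep$windows$val, sc)
  te <- apply_scaler(prep$windows$test, sc)
  spec <- small_cnn()
  tc <- train_config("cnn", max_epochs = 3L, seed = 1L)
  src <- train_model(build_model(spec, dim(tr$x)[2:3], seed = 1L), tr, va, tc)

  ft_cfg <- finetune_config("cnn", train_config("cnn", max_epochs = 3L, seed = 2L))
  run <- run_finetune(src, tr, va, te, ft_cfg)
  for (nm in src$embed_params) {
    expect_identical(run$model$params[[nm]], src$params[[nm]])
  }
  # head parameters moved
  expect_false(identical(run$model$params$headW, src$params$headW))
  # embeddings identical on arbitrary inputs
  x <- array(rnorm(5 * prod(dim(tr$x)[2:3])), c(5, dim(tr$x)[2:3]))
  expect_identical(embed_windows(run$model, x), embed_windows(src, x))
  # scheduler factor override
  expect_equal(ft_cfg$sched_factor, 0.75)
  expect_equal(finetune_config("lstm")$sched_factor, 0.7)
})

test_that("fine-tuning with a zero-epoch budget reduces to generalization", {
  prep <- fx_prep(seed = 3L, n = 300L)
  sc <- prep$scaler
  tr <- apply_scaler(prep$windows$train, sc)
  va <- apply_scaler(prep$windows$val, sc)
  te <- apply_scaler(prep$windows$test, sc)
  tc <- train_config("cnn", max_epochs = 2L, seed = 1L)
  src <- train_model(build_model(small_cnn(), dim(tr$x)[2:3], seed = 1L), tr, va, tc)
  zero <- train_config("cnn", max_epochs = 0L, seed = 1L)
  run <- run_finetune(src, tr, va, te, zero)
  gen <- run_generalization(src, te)
  expect_equal(run$result$auroc, gen$result$auroc)
  expect_identical(run$model$params, src$params)
})

test_that("retraining starts from the source weights and applies the overrides", {
  rc <- retrain_config("cnn")
  expect_equal(rc$config$lr, 0.001)
  expect_equal(rc$config$sched_factor, 0.09)
  expect_equal(rc$spec_overrides$dropout, 0.6)
  expect_true(rc$spec_overrides$extra_dropout)
  expect_equal(retrain_config("lstm")$config$lr, 1e-4)
  expect_equal(retrain_config("lstm")$spec_overrides$dropout, 0.6)
  expect_equal(retrain_config("inceptiontime")$spec_overrides$dropout, 0.7)
  expect_equal(retrain_config("inceptiontime")$config$sched_factor, 0.09)

  # zero learning rate: retraining is a no-op on the parameters
  prep <- fx_prep(seed = 3L, n = 300L)
  sc <- prep$scaler
  tr <- apply_scaler(prep$windows$train, sc)
  va <- apply_scaler(prep$windows$val, sc)
  te <- apply_scaler(prep$windows$test, sc)
  tc <- train_config("cnn", max_epochs = 2L, seed = 1L)
  src <- train_model(build_model(small_cnn(), dim(tr$x)[2:3], seed = 1L), tr, va, tc)
  cfg0 <- train_config("cnn", lr = 0, min_lr = 0, max_epochs = 2L, seed = 3L)
  run <- run_retrain(src, tr, va, te, cfg0)
  expect_identical(run$model$params, src$params)
})

test_that("fusion bookkeeping: empty target subset reduces to source training", {
  prep <- fx_prep(seed = 3L, n = 300L)
  sc <- prep$scaler
  tr <- apply_scaler(prep$windows$train, sc)
  va <- apply_scaler(prep$windows$val, sc)
  te <- apply_scaler(prep$windows$test, sc)
  empty <- filter_windows(tr, integer())
  tc <- train_config("cnn", max_epochs = 2L, seed = 4L)
  fus <- run_fusion(small_cnn(), tr, empty, va, te, tc)
  direct <- train_model(build_model(small_cnn(), dim(tr$x)[2:3], seed = 4L),
                        tr, va, tc)
  expect_identical(fus$model$params, direct$params)

  # pooled training-set size is the sum of its parts
  sub <- filter_windows(tr, unique(tr$provenance$stay_id)[1:5])
  pooled <- bind_windows(tr, sub)
  expect_equal(n_windows(pooled), n_windows(tr) + n_windows(sub))
})

test_that("strategies consume identical target test sets (digest check)", {
  prep <- fx_prep(seed = 3L, n = 300L)
  sc <- prep$scaler
  tr <- apply_scaler(prep$windows$train, sc)
  va <- apply_scaler(prep$windows$val, sc)
  te <- apply_scaler(prep$windows$test, sc)
  tc <- train_config("cnn", max_epochs = 1L, seed = 1L)
  src <- train_model(build_model(small_cnn(), dim(tr$x)[2:3], seed = 1L), tr, va, tc)
  sub <- filter_windows(tr, unique(tr$provenance$stay_id)[1:10])
  runs <- list(
    run_generalization(src, te),
    run_target_training(small_cnn(), sub, va, te, tc),
    run_finetune(src, sub, va, te, train_config("cnn", max_epochs = 1L, seed = 1L)),
    run_retrain(src, sub, va, te, train_config("cnn", max_epochs = 1L, seed = 1L))
  )
  digests <- purrr::map_chr(runs, ~ .x$result$data_digest)
  expect_equal(length(unique(digests)), 1L)
  # evaluating generalization twice gives identical results
  expect_identical(run_generalization(src, te)$result,
                   runs[[1]]$result)
})

test_that("joint domain-adaptation training runs with both alignment losses", {
  prep <- fx_prep(seed = 3L, n = 300L)
  sc <- prep$scaler
  tr <- apply_scaler(prep$windows$train, sc)
  va <- apply_scaler(prep$windows$val, sc)
  te <- apply_scaler(prep$windows$test, sc)
  # a small target domain forces the cycling of the smaller domain
  sub <- filter_windows(tr, unique(tr$provenance$stay_id)[1:30])
  tc <- train_config("cnn", max_epochs = 2L, seed = 6L)
  for (method in c("mmd", "coral")) {
    run <- run_da(small_cnn(), tr, sub, va, te,
                  da = da_config(method, "cnn"), config = tc, fraction = 0.1)
    expect_equal(run$result$strategy, paste0("da_", method))
    expect_true(run$result$auroc >= 0 && run$result$auroc <= 1)
    expect_gt(run$result$nauprc, 0)
    expect_equal(nrow(run$model$history), 2L)
    # deterministic under the same seed
    run2 <- run_da(small_cnn(), tr, sub, va, te,
                   da = da_config(method, "cnn"), config = tc, fraction = 0.1)
    expect_identical(run$model$params, run2$model$params)
  }
})

test_that("generalization refuses unscaled windows and target training refuses empty ones", {
  prep <- fx_prep(seed = 3L, n = 300L)
  tc <- train_config("cnn", max_epochs = 1L, seed = 1L)
  sc <- prep$scaler
  tr <- apply_scaler(prep$windows$train, sc)
  va <- apply_scaler(prep$windows$val, sc)
  src <- train_model(build_model(small_cnn(), dim(tr$x)[2:3], seed = 1L), tr, va, tc)
  expect_error(run_generalization(src, prep$windows$test), "scaled")
  empty <- filter_windows(tr, integer())
  expect_error(run_target_training(small_cnn(), empty, va, tr, tc), "empty")
  expect_error(train_da(build_model(small_cnn(), dim(tr$x)[2:3]), empty, tr, va,
                        da_config("mmd", "cnn"), tc), "non-empty")
})
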