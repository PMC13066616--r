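# Shared fixtures. Expensive objects are memoized so several test files can
# reuse one generation/preparation.

fx_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, fx_cache)) assign(key, force(expr), fx_cache)
  get(key, fx_cache)
}

# compact site config: 6 features (4 informative vitals), short stays
tiny_config <- function(seed = 3L, ...) {
  site_config(n_features = 6L, seed = seed, stay_mean_extra = 12,
              stay_max = 60L, ...)
}

# strong heterogeneous covariate shift used by the directional checks
strong_shift <- function() {
  list(shift_d = c(hr = 2, map = -2, resp = 2, temp = -2),
       var_ratio = c(hr = 4, map = 0.25, resp = 0.25, temp = 4))
}

# wider val/test fractions so model selection and evaluation see enough
# septic stays at small cohort sizes
eval_fractions <- c(train = 0.6, val = 0.2, test = 0.2)

fx_site <- function(seed = 3L, n = 300L) {
  memo(paste0("site_", seed, "_", n), generate_site(tiny_config(seed), n))
}

fx_prep <- function(seed = 3L, n = 300L) {
  memo(paste0("prep_", seed, "_", n), prepare_site(fx_site(seed, n)$cohort))
}

small_cnn <- function() model_spec("cnn", conv_channels = c(8L, 16L, 16L))

# hand-built miniature cohort with fully controlled events, for labeling and
# schema tests
toy_cohort <- function(spans = c(`1` = 48L, `2` = 30L),
                       abx = NULL, cultures = NULL, organ = NULL,
                       n_features = 2L) {
  ids <- as.integer(names(spans))
  static <- tibble::tibble(
    stay_id = ids, admission_time = as.numeric(seq_along(ids)),
    age = 60, sex = 1, height = 170, weight = 70
  )
  dyn <- purrr::list_rbind(purrr::map(ids, function(s) {
    L <- spans[[as.character(s)]]
    tibble::tibble(stay_id = s, hour = 0:(L - 1L),
                   f1 = as.numeric(seq_len(L)), f2 = 0)
  }))
  if (is.null(organ)) {
    organ <- purrr::list_rbind(purrr::map(ids, function(s) {
      L <- spans[[as.character(s)]]
      tibble::tibble(stay_id = s, hour = 0:(L - 1L), score = 2L)
    }))
  }
  cohort_table(static, dyn, abx, cultures, organ,
               features = c("f1", "f2"), validate = FALSE)
}

params_digest <- function(model) rlang::hash(model$params)

# independent brute-force oracles for the threshold-free metrics
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

auprc_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels)
    fp <- sum(scores >= t & !labels)
    prec <- tp / (tp + fp)
    rec <- tp / sum(labels)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# one seed of the directional strategy comparison on a strong-shift pair:
# source-trained generalization, target training at 100% and 5%, and
# retraining from the source model at 5%
directional_run <- function(seed) {
  memo(paste0("directional_", seed), {
    sh <- strong_shift()
    cfg <- tiny_config(seed)
    pair <- generate_pair(cfg, sh$shift_d, sh$var_ratio,
                          n_source = 400L, n_target = 400L)
    ps <- prepare_site(pair$source$cohort, fractions = eval_fractions)
    pt <- prepare_site(pair$target$cohort, fractions = eval_fractions)
    spec <- small_cnn()
    tc <- train_config("cnn", max_epochs = 15L, seed = seed)
    ss <- ps$scaler
    src_tr <- apply_scaler(ps$windows$train, ss)
    src_va <- apply_scaler(ps$windows$val, ss)
    src <- train_model(build_model(spec, dim(src_tr$x)[2:3], seed = seed),
                       src_tr, src_va, tc)
    te_src <- apply_scaler(pt$windows$test, ss)
    gen <- run_generalization(src, te_src)$result$auroc

    st <- fit_scaler(pt$windows$train)
    tr <- apply_scaler(pt$windows$train, st)
    va <- apply_scaler(pt$windows$val, st)
    te <- apply_scaler(pt$windows$test, st)
    t100 <- run_target_training(spec, tr, va, te, tc)$result$auroc

    tids <- pt$split$stay_id[pt$split$split == "train"]
    subs <- nested_subsets(tids, pt$outcomes, fractions = c(0.05, 1),
                           seed = seed + 17L)
    sub_raw <- filter_windows(pt$windows$train, subs[[1]])
    st5 <- fit_scaler(sub_raw)
    t5 <- run_target_training(
      spec, apply_scaler(sub_raw, st5),
      apply_scaler(pt$windows$val, st5),
      apply_scaler(pt$windows$test, st5), tc, fraction = 0.05
    )$result$auroc

    re5 <- run_retrain(
      src, apply_scaler(sub_raw, ss),
      apply_scaler(pt$windows$val, ss), te_src,
      config = retrain_config("cnn", train_config("cnn", max_epochs = 15L,
                                                  seed = seed))$config,
      fraction = 0.05
    )$result$auroc

    list(gen = gen, t100 = t100, t5 = t5, re5 = re5)
  })
}
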