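#' Configure a desk-scale deployment-strategy experiment
#'
#' Describes a full experiment over one synthetic source/target pair: which
#' architectures, strategies, target-data fractions, and seeds to run. The
#' generator settings define the study conditions; the architecture presets
#' here are deliberately small so the full grid runs on a single CPU.
#'
#' @param reference [site_config()] of the source site (its seed also fixes
#'   both generated cohorts).
#' @param shift_d,var_ratio Covariate shift of the target site
#'   (see [induce_shift()]).
#' @param n_source,n_target Stays per site.
#' @param archs Architectures to run (subset of cnn/lstm/inceptiontime).
#' @param strategies Strategies to run (subset of target, fusion, finetune,
#'   retrain, da_mmd, da_coral; generalization is always evaluated once per
#'   architecture and seed).
#' @param fractions Target-data fraction ladder, strictly increasing and
#'   ending at 1 (default `c(0.05, 0.1, 0.2, 0.5, 0.75, 1)`).
#' @param seeds Integer training seeds (>= 1 of them).
#' @param specs Named list of [model_spec()]s per architecture; defaults to
#'   compact presets (CNN 8/16/16 channels, LSTM hidden 16, InceptionTime
#'   depth 3, filters 4).
#' @param max_epochs Epoch cap applied to every training run (default 20).
#' @param out_dir Optional directory for cached results; re-runs skip
#'   completed cells and refuse to mix configurations.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(reference = site_config(n_features = 8L, seed = 1L),
                              shift_d = 0.8, var_ratio = 1.5,
                              n_source = 400L, n_target = 400L,
                              archs = "cnn",
                              strategies = c("target", "fusion", "finetune",
                                             "retrain", "da_mmd", "da_coral"),
                              fractions = c(0.05, 0.1, 0.2, 0.5, 0.75, 1),
                              seeds = 1L,
                              specs = NULL,
                              max_epochs = 20L,
                              out_dir = NULL) {
  if (any(diff(fractions) <= 0) || abs(tail(fractions, 1) - 1) > 1e-8) {
    abort("fractions must be strictly increasing and end at 1.0",
          class = "sepshift_config_error")
  }
  if (length(seeds) < 1) abort("at least one seed is required")
  known <- c("target", "fusion", "finetune", "retrain", "da_mmd", "da_coral")
  bad <- setdiff(strategies, known)
  if (length(bad) > 0) abort(paste("unknown strategies:", paste(bad, collapse = ", ")))
  if (is.null(specs)) {
    specs <- list(
      cnn = model_spec("cnn", conv_channels = c(8L, 16L, 16L)),
      lstm = model_spec("lstm", hidden = 16L),
      inceptiontime = model_spec("inceptiontime", depth = 3L, filters = 4L,
                                 bottleneck = 4L)
    )
  }
  structure(list(reference = reference, shift_d = shift_d,
                 var_ratio = var_ratio,
                 n_source = as.integer(n_source), n_target = as.integer(n_target),
                 archs = archs, strategies = strategies,
                 fractions = fractions, seeds = as.integer(seeds),
                 specs = specs, max_epochs = as.integer(max_epochs),
                 out_dir = out_dir),
            class = "experiment_config")
}

config_digest <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

scale_set <- function(ws, scaler) apply_scaler(ws, scaler)

#' Run the full strategy-comparison pipeline
#'
#' Generates the site pair, labels it, preprocesses both sites, trains the
#' source models, runs every requested (architecture, strategy, fraction,
#' seed) cell plus a generalization row per architecture and seed, and
#' computes the covariate-shift report. Each run is stamped with the
#' experiment's config digest; with `out_dir` set, completed cells are
#' skipped on re-runs and a digest mismatch is refused.
#'
#' Normalization follows each strategy's training data: target training uses
#' a scaler fit on its subset, fusion and domain adaptation refit on the
#' pooled training windows, fine-tuning/retraining/generalization reuse the
#' source scaler the pre-trained weights assume.
#'
#' @param config An [experiment_config()].
#' @return List with `results` (one row per strategy run), `shift`
#'   (a [shift_report()]), `sites`, and `preps` (invisible heavy objects are
#'   omitted when caching).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  digest <- config_digest(config)
  cache_file <- NULL
  done <- tibble()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    dig_file <- file.path(config$out_dir, "config_digest.txt")
    cache_file <- file.path(config$out_dir, "results.csv")
    if (file.exists(dig_file)) {
      old <- readLines(dig_file, warn = FALSE)[1]
      if (!identical(old, digest)) {
        abort(paste0("out_dir holds results for a different configuration ",
                     "(digest ", old, " != ", digest, "); ",
                     "use a fresh out_dir or delete the old results"),
              class = "sepshift_config_error")
      }
      if (file.exists(cache_file)) {
        done <- readr::read_csv(cache_file, show_col_types = FALSE)
      }
    } else {
      writeLines(digest, dig_file)
    }
  }

  pair <- generate_pair(config$reference, config$shift_d, config$var_ratio,
                        config$n_source, config$n_target)
  prep_s <- prepare_site(pair$source$cohort)
  prep_t <- prepare_site(pair$target$cohort)
  shift <- shift_report(pair$source$cohort$dynamic, pair$target$cohort$dynamic)

  t_train_ids <- prep_t$split$stay_id[prep_t$split$split == "train"]
  results <- list()
  if (nrow(done) > 0) results[[1]] <- done
  is_done <- function(strategy, arch, fraction, seed) {
    nrow(done) > 0 && any(
      done$strategy == strategy & done$arch == arch &
        (is.na(fraction) | abs(done$target_fraction - fraction) < 1e-9 |
           is.na(done$target_fraction)) &
        done$seed == seed
    )
  }

  for (arch in config$archs) {
    spec <- config$specs[[arch]]
    for (seed in config$seeds) {
      tc <- train_config(arch, max_epochs = config$max_epochs, seed = seed)
      src_scaler <- prep_s$scaler
      src_train <- scale_set(prep_s$windows$train, src_scaler)
      src_val <- scale_set(prep_s$windows$val, src_scaler)
      # the source model backs generalization, fine-tuning, and retraining
      src_model <- build_model(spec, dim(src_train$x)[2:3], seed = seed)
      src_model <- train_model(src_model, src_train, src_val, tc)

      if (!is_done("generalization", arch, NA, seed)) {
        tgt_test_src <- scale_set(prep_t$windows$test, src_scaler)
        gen <- run_generalization(src_model, tgt_test_src, "source", "target")
        row <- gen$result
        row$target_stays <- 0L
        results[[length(results) + 1]] <- row
      }

      subsets <- nested_subsets(t_train_ids, prep_t$outcomes,
                                fractions = config$fractions,
                                seed = seed + 17L)
      for (fi in seq_along(config$fractions)) {
        f <- config$fractions[fi]
        ids <- subsets[[fi]]
        t_sub_raw <- filter_windows(prep_t$windows$train, ids)
        n_sub_stays <- length(ids)
        for (strategy in config$strategies) {
          if (is_done(strategy, arch, f, seed)) next
          run <- run_one_strategy(strategy, spec, tc, src_model, src_scaler,
                                  prep_s, prep_t, t_sub_raw, f, seed)
          row <- run$result
          row$target_stays <- n_sub_stays
          results[[length(results) + 1]] <- row
        }
      }
    }
  }
  results <- list_rbind(results)
  results$config_digest <- digest
  if (!is.null(cache_file)) {
    readr::write_csv(results, cache_file)
  }
  list(results = results, shift = shift,
       sites = pair, preps = list(source = prep_s, target = prep_t))
}

run_one_strategy <- function(strategy, spec, tc, src_model, src_scaler,
                             prep_s, prep_t, t_sub_raw, fraction, seed) {
  if (strategy == "target") {
    sc <- fit_scaler(t_sub_raw)
    return(run_target_training(
      spec,
      scale_set(t_sub_raw, sc),
      scale_set(prep_t$windows$val, sc),
      scale_set(prep_t$windows$test, sc),
      tc, fraction, "source", "target"
    ))
  }
  if (strategy == "fusion") {
    pooled_raw <- if (n_windows(t_sub_raw) == 0) prep_s$windows$train
                  else bind_windows(prep_s$windows$train, t_sub_raw)
    sc <- fit_scaler(pooled_raw)
    return(run_fusion(
      spec,
      scale_set(prep_s$windows$train, sc),
      scale_set(t_sub_raw, sc),
      scale_set(prep_t$windows$val, sc),
      scale_set(prep_t$windows$test, sc),
      tc, fraction, "source", "target"
    ))
  }
  if (strategy == "finetune") {
    cfg <- finetune_config(spec$arch, tc)
    return(run_finetune(
      src_model,
      scale_set(t_sub_raw, src_scaler),
      scale_set(prep_t$windows$val, src_scaler),
      scale_set(prep_t$windows$test, src_scaler),
      cfg, fraction, "source", "target"
    ))
  }
  if (strategy == "retrain") {
    cfg <- retrain_config(spec$arch, tc)$config
    return(run_retrain(
      src_model,
      scale_set(t_sub_raw, src_scaler),
      scale_set(prep_t$windows$val, src_scaler),
      scale_set(prep_t$windows$test, src_scaler),
      cfg, fraction, "source", "target"
    ))
  }
  if (strategy %in% c("da_mmd", "da_coral")) {
    method <- sub("^da_", "", strategy)
    pooled_raw <- bind_windows(prep_s$windows$train, t_sub_raw)
    sc <- fit_scaler(pooled_raw)
    return(run_da(
      spec,
      scale_set(prep_s$windows$train, sc),
      scale_set(t_sub_raw, sc),
      scale_set(prep_t$windows$val, sc),
      scale_set(prep_t$windows$test, sc),
      da = da_config(method, spec$arch),
      config = tc, fraction = fraction,
      source_id = "source", target_id = "target"
    ))
  }
  abort(paste("unknown strategy:", strategy))
}

#' Strategy performance curves
#'
#' AUROC (or any metric) against the target-data fraction, one line per
#' strategy, with the generalization baseline as a dashed horizontal line.
#'
#' @param results Strategy-result rows from [run_pipeline()].
#' @param metric Result column to plot (default `"auroc"`).
#' @return A ggplot object.
#' @export
plot_strategy_curves <- function(results, metric = "auroc") {
  gen <- results |> filter(.data$strategy == "generalization")
  df <- results |> filter(.data$strategy != "generalization") |>
    summarise(score = mean(.data[[metric]]),
              .by = c("strategy", "target_fraction"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$target_fraction,
                                        y = .data$score,
                                        colour = .data$strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "target training fraction", y = metric) +
    ggplot2::theme_minimal()
  if (nrow(gen) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = mean(gen[[metric]]),
                                 linetype = "dashed", colour = "brown")
  }
  p
}
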