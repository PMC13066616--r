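mk_outcomes <- function(n, septic_ids) {
  tibble::tibble(stay_id = seq_len(n), septic = seq_len(n) %in% septic_ids)
}

mk_static <- function(n, admission = seq_len(n)) {
  tibble::tibble(stay_id = seq_len(n), admission_time = as.numeric(admission))
}

test_that("temporal split gives 80/10/10 with every split represented", {
  n <- 100L
  oc <- mk_outcomes(n, c(10L, 30L, 50L, 70L, 90L))  # septic spread uniformly
  sp <- temporal_split(mk_static(n), oc)
  expect_equal(as.integer(table(sp$split)), c(80L, 10L, 10L))
  counts <- dplyr::left_join(sp, oc, by = "stay_id") |>
    dplyr::summarise(k = sum(.data$septic), .by = "split")
  expect_true(all(counts$k >= 0))
  expect_equal(sum(counts$k), 5L)
})

test_that("temporal ties are broken by stay_id and the split is deterministic", {
  n <- 20L
  oc <- mk_outcomes(n, c(4L, 15L))
  st <- mk_static(n, admission = rep(0, n))
  sp1 <- temporal_split(st, oc)
  sp2 <- temporal_split(st, oc)
  expect_identical(sp1, sp2)
  expect_equal(as.integer(table(sp1$split)), c(16L, 2L, 2L))
  # with equal timestamps, block order follows stay_id order
  expect_equal(sp1$stay_id[sp1$split == "train"][1:3], 1:3)
})

test_that("split sizes use largest-remainder rounding", {
  oc <- mk_outcomes(9L, integer())
  sp <- temporal_split(mk_static(9L), oc)
  expect_equal(as.integer(table(sp$split)), c(7L, 1L, 1L))
  expect_error(temporal_split(mk_static(9L), oc, fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("boundary swaps restore label balance in unbalanced temporal blocks", {
  # all septic stays admitted early: a plain temporal cut puts them all in train
  n <- 200L
  oc <- mk_outcomes(n, 1:20)
  sp <- temporal_split(mk_static(n), oc, tolerance = 0.02)
  df <- dplyr::left_join(sp, oc, by = "stay_id")
  frac <- df |> dplyr::summarise(f = mean(.data$septic), .by = "split")
  overall <- 0.1
  sizes <- table(sp$split)
  for (i in seq_len(nrow(frac))) {
    slack <- max(0.02, 1 / sizes[[as.character(frac$split[i])]])
    expect_lte(abs(frac$f[i] - overall), slack + 1e-9)
  }
})

test_that("nested subsets are strictly nested, stratified, and reproducible", {
  oc <- mk_outcomes(1000L, seq(1L, 1000L, by = 20L))  # 50 septic
  ids <- oc$stay_id
  subs <- nested_subsets(ids, oc, seed = 4L)
  fr <- c(0.05, 0.10, 0.20, 0.50, 0.75, 1.0)
  for (i in seq_along(subs)[-1]) {
    expect_true(all(subs[[i - 1]] %in% subs[[i]]))
  }
  expect_equal(length(subs[[2]]), 100L)
  expect_equal(sum(subs[[2]] %in% oc$stay_id[oc$septic]), 5L)
  expect_identical(subs, nested_subsets(ids, oc, seed = 4L))
  expect_false(identical(subs, nested_subsets(ids, oc, seed = 5L)))
  expect_error(nested_subsets(ids, oc, fractions = c(0.5, 0.2, 1)), "increasing")
})

test_that("nesting holds across fraction ladders and seeds", {
  oc <- mk_outcomes(173L, sample.int(173L, 11L))
  for (seed in 1:5) {
    fr <- sort(runif(4, 0.05, 0.9))
    fr <- c(fr, 1.0)
    subs <- nested_subsets(oc$stay_id, oc, fractions = fr, seed = seed)
    for (i in seq_along(subs)[-1]) {
      expect_true(all(subs[[i - 1]] %in% subs[[i]]))
    }
    expect_setequal(subs[[length(subs)]], oc$stay_id)
    # stratification within one stay of the proportional count
    n_sep <- sum(oc$septic)
    for (i in seq_along(fr)) {
      got <- sum(subs[[i]] %in% oc$stay_id[oc$septic])
      expect_lte(abs(got - fr[i] * n_sep), 1 + 1e-9)
    }
  }
})

test_that("flag-and-impute follows forward fill with train-mean backstop", {
  dyn <- tibble::tibble(stay_id = c(1L, 1L, 1L, 2L, 2L),
                        hour = c(0L, 1L, 2L, 0L, 1L),
                        f = c(7, NA, NA, NA, 3))
  out <- flag_and_impute(dyn, c(f = 5))
  expect_equal(out$f, c(7, 7, 7, 5, 3))
  expect_equal(out$f_missing, c(0L, 1L, 1L, 1L, 0L))

  # no missing values: flags all zero, values unchanged
  dyn2 <- dplyr::mutate(dyn, f = 1:5 / 2)
  out2 <- flag_and_impute(dyn2, c(f = 5))
  expect_equal(out2$f, dyn2$f)
  expect_true(all(out2$f_missing == 0L))

  expect_error(flag_and_impute(dyn, c(g = 1), features = "f"),
               class = "sepshift_config_error")
})

test_that("imputation never leaks across stay boundaries", {
  dyn <- tibble::tibble(stay_id = c(1L, 1L, 2L, 2L),
                        hour = c(0L, 1L, 0L, 1L),
                        f = c(9, 9, NA, NA))
  out <- flag_and_impute(dyn, c(f = -1))
  expect_equal(out$f[3:4], c(-1, -1))  # train mean, not stay 1's value
})

test_that("scaler is learned on training windows only and clamps constants", {
  x <- array(0, c(2, 1, 2))
  x[, 1, 1] <- c(1, 3)      # mean 2, var 1
  x[, 1, 2] <- c(5, 5)      # constant channel
  ws <- sepshift:::new_window_set(x, c(TRUE, FALSE),
                                  tibble::tibble(stay_id = 1:2, end_hour = 0L),
                                  c("a", "b"))
  expect_warning(params <- fit_scaler(ws), "constant")
  expect_equal(params$mean, c(2, 5))
  expect_equal(params$var, c(1, 1))
  scaled <- apply_scaler(ws, params)
  expect_equal(as.numeric(scaled$x[, 1, 1]), c(-1, 1))

  # training params applied to other data leave a nonzero mean in general
  x2 <- x; x2[, 1, 1] <- c(10, 20)
  ws2 <- sepshift:::new_window_set(x2, c(TRUE, FALSE), ws$provenance, ws$channels)
  expect_gt(abs(mean(apply_scaler(ws2, params)$x[, 1, 1])), 1)

  expect_error(fit_scaler(filter_windows(ws, integer())), "empty")
})

test_that("windowing counts, labels, and provenance follow the 6-hour rule", {
  site <- fx_site(seed = 3L, n = 60L)
  lab <- label_cohort(site$cohort)
  dyn <- site$cohort$dynamic |>
    dplyr::filter(.data$stay_id %in% lab$kept_stays)
  means <- train_feature_means(dyn, unique(dyn$stay_id), site$cohort$features)
  imp <- flag_and_impute(dyn, means)
  ws <- make_windows(imp, lab$labels)
  spans <- stay_spans(site$cohort) |>
    dplyr::filter(.data$stay_id %in% lab$kept_stays)
  expect_equal(n_windows(ws), sum(pmax(0, spans$span - 5)))
  expect_false("stay_id" %in% ws$channels)
  expect_false("hour" %in% ws$channels)
  # window label equals the hourly label at the end hour
  joined <- dplyr::left_join(ws$provenance |>
                               dplyr::mutate(label = ws$label),
                             lab$labels,
                             by = c("stay_id", "end_hour" = "hour"))
  expect_equal(joined$label.x, joined$label.y)
})

test_that("a 24-hour stay yields 19 windows and short stays none", {
  dyn <- tibble::tibble(stay_id = 1L, hour = 0:23, f = rnorm(24), f_missing = 0L)
  labs <- tibble::tibble(stay_id = 1L, hour = 0:23, label = FALSE)
  ws <- make_windows(dyn, labs)
  expect_equal(n_windows(ws), 19L)
  expect_equal(range(ws$provenance$end_hour), c(5L, 23L))

  short <- dplyr::filter(dyn, hour < 5)
  expect_equal(n_windows(make_windows(short, labs)), 0L)
})

test_that("windows composed with label blocks mark end hours 14..33 positive", {
  onsets <- tibble::tibble(stay_id = 1L, onset_hour = 20L,
                           excluded = FALSE, exclusion_reason = "none")
  spans <- tibble::tibble(stay_id = 1L, span = 49L)
  labs <- build_labels(onsets, spans)
  dyn <- tibble::tibble(stay_id = 1L, hour = 0:48, f = 0, f_missing = 0L)
  ws <- make_windows(dyn, labs)
  pos_ends <- ws$provenance$end_hour[ws$label]
  expect_equal(pos_ends, 14:33)
})

test_that("preprocessing statistics depend on the training partition only", {
  prep <- fx_prep(seed = 3L, n = 300L)
  site <- fx_site(seed = 3L, n = 300L)
  lab <- label_cohort(site$cohort)
  train_ids <- prep$split$stay_id[prep$split$split == "train"]
  dyn <- site$cohort$dynamic |>
    dplyr::filter(.data$stay_id %in% lab$kept_stays)
  # recompute means from the training partition alone
  means2 <- train_feature_means(dyn, train_ids, site$cohort$features)
  expect_equal(prep$train_means, means2)
  # and from the training windows alone for the scaler
  expect_equal(prep$scaler, fit_scaler(prep$windows$train))
  # subsets drawn from training stays only
  subs <- nested_subsets(train_ids, prep$outcomes, seed = 11L)
  expect_true(all(unlist(subs) %in% train_ids))
})
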