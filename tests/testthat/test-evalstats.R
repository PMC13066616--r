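test_that("AUROC and AUPRC agree with brute-force oracles on all small inputs", {
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    labels <- rep(FALSE, n)
    labels[sample(n, sample(n - 1, 1))] <- TRUE
    if (!any(labels) || all(labels)) next
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
    m <- compute_metrics(scores, labels)
    expect_equal(m$auroc, auroc_oracle(scores, labels))
    expect_equal(m$auprc, auprc_oracle(scores, labels))
  }
})

test_that("nAUPRC is AUPRC over prevalence with its analytic extremes", {
  m <- compute_metrics(c(0.9, 0.8, 0.3, 0.2, 0.1, 0.05, 0.04, 0.03, 0.02, 0.01),
                       c(TRUE, FALSE, rep(FALSE, 8)))
  expect_equal(m$nauprc, m$auprc / 0.1)

  # perfect separation at prevalence 0.1: AUROC 1, nAUPRC 10
  scores <- c(rep(0.9, 2), rep(0.1, 18))
  labels <- c(rep(TRUE, 2), rep(FALSE, 18))
  mp <- compute_metrics(scores, labels)
  expect_equal(mp$auroc, 1)
  expect_equal(mp$nauprc, 10)

  expect_error(compute_metrics(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("random scores give nAUPRC near 1 in expectation at any prevalence", {
  for (prev in c(0.01, 0.05, 0.2)) {
    n <- round(2000 / prev)   # hold the positive count fixed across prevalences
    vals <- purrr::map_dbl(1:3, function(seed) {
      set.seed(seed)
      labels <- runif(n) < prev
      compute_metrics(runif(n), labels)$nauprc
    })
    expect_lt(abs(mean(vals) - 1), 0.1)
  }
})

test_that("per-stay summaries compute the four statistics per feature", {
  dyn <- tibble::tibble(stay_id = c(1L, 1L, 1L, 2L, 3L),
                        hour = c(0L, 1L, 2L, 0L, 0L),
                        a = c(1, 2, 3, 4, NA),
                        b = c(NA, NA, NA, 1, 2))
  s <- per_stay_summaries(dyn)
  expect_equal(sort(setdiff(names(s), "stay_id")),
               sort(c("a_mean", "a_var", "a_min", "a_max",
                      "b_mean", "b_var", "b_min", "b_max")))
  expect_equal(s$a_mean[1], 2)
  expect_equal(s$a_var[1], 1)      # sample variance
  expect_equal(s$a_min[1], 1)
  expect_equal(s$a_max[1], 3)
  expect_true(is.na(s$a_var[2]))   # single observation: variance undefined
  expect_true(is.na(s$a_mean[3]))  # no observations: all four missing
  expect_true(is.na(s$b_var[1]))
})

test_that("a 48-feature cohort yields exactly 192 summary columns", {
  cfg <- site_config(seed = 19L, stay_mean_extra = 6, stay_max = 36L)
  site <- generate_site(cfg, 30L)
  s <- per_stay_summaries(site$cohort$dynamic)
  expect_equal(ncol(s) - 1L, 192L)
})

test_that("K-S shift testing flags identical columns as null and respects BH", {
  set.seed(5)
  a <- tibble::tibble(stay_id = 1:60, f_mean = rnorm(60), f_var = rexp(60),
                      f_min = rnorm(60) - 2, f_max = rnorm(60) + 2)
  res_same <- ks_shift_test(a, a)
  expect_true(all(res_same$ks_stat == 0))
  expect_true(all(res_same$p_value == 1))
  expect_false(any(res_same$significant))

  # BH monotonicity: adjusted p never below raw p, ordering preserved
  b <- dplyr::mutate(a, f_mean = f_mean + 2)
  res <- ks_shift_test(a, b)
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adj[o]) >= -1e-12))
  expect_true(res$significant[res$column == "f_mean"])

  # untestable columns are excluded from the BH family
  a2 <- dplyr::mutate(a, f_var = NA_real_)
  expect_message(res2 <- ks_shift_test(a2, dplyr::mutate(b, f_var = NA_real_)),
                 "untestable")
  expect_false(res2$testable[res2$column == "f_var"])
})

test_that("Cohen's d matches analytic cases and bins at 0.2/0.5/0.8", {
  x <- tibble::tibble(stay_id = 1:100, f_mean = as.numeric(scale(rnorm(100))))
  y <- dplyr::mutate(x, f_mean = f_mean + 1)
  d <- cohens_d(x, y)
  expect_equal(d$cohens_d, 1, tolerance = 1e-9)
  expect_equal(as.character(d$effect_bin), "large")

  expect_equal(as.character(sepshift:::effect_size_bin(c(0.1, 0.2, 0.49, 0.5, 0.79, 0.8, 2))),
               c("negligible", "small", "small", "medium", "medium", "large", "large"))

  same <- cohens_d(x, x)
  expect_equal(same$cohens_d, 0)
  expect_equal(as.character(same$effect_bin), "negligible")

  const <- tibble::tibble(stay_id = 1:10, f_mean = rep(1, 10))
  expect_true(is.na(cohens_d(const, const)$cohens_d))
})

test_that("size bins follow the 8000/32000 stay thresholds", {
  expect_equal(as.character(size_bin(c(5000, 8000, 8001, 32000, 32001, 40000))),
               c("small", "small", "medium", "medium", "large", "large"))
  expect_error(size_bin(-1), "non-negative")
})

test_that("paired Wilcoxon ranking reproduces the exact reference cases", {
  # identical strategies: tied means, p = 1
  s <- matrix(rep(1:12 / 12, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  rt <- rank_strategies(s)
  expect_equal(rt$pairs$p_value, 1)
  expect_equal(rt$pairs$tier, factor("", levels = c("***", "**", "*", "")))

  # a beats b on all 12 matched runs: exact two-sided p = 2 / 2^12,
  # Bonferroni over 15 pairs leaves it inside the 0.05 tier
  set.seed(2)
  base <- runif(12)
  s2 <- rbind(a = base + seq(0.01, 0.12, by = 0.01), b = base)  # a wins all 12
  rt2 <- rank_strategies(s2, n_pairs = 15)
  expect_equal(rt2$pairs$p_value, 2 / 2^12, tolerance = 1e-12)
  expect_equal(rt2$pairs$p_adj, 15 * 2 / 2^12, tolerance = 1e-12)
  expect_lt(rt2$pairs$p_adj, 0.05)
  expect_equal(as.character(rt2$pairs$tier), "**")  # 0.00732 also clears 0.01
  expect_equal(rt2$ranking$strategy, c("a", "b"))

  # six strategies: 15 pairwise tests, ranks a permutation of 1..6
  s6 <- matrix(rnorm(6 * 12), 6, 12,
               dimnames = list(paste0("s", 1:6), NULL))
  rt6 <- rank_strategies(s6)
  expect_equal(nrow(rt6$pairs), 15L)
  expect_setequal(rt6$ranking$rank, 1:6)
  expect_equal(rt6$ranking$strategy[1],
               names(which.max(rowMeans(s6))))
})

test_that("matched score collection yields one entry per pair x architecture", {
  grid <- tidyr::expand_grid(
    strategy = c("target", "retrain", "fusion"),
    source = c("A", "B"), target = c("X", "Y"),
    arch = c("cnn", "lstm", "inceptiontime"),
    target_fraction = c(0.05, 0.1)
  ) |>
    dplyr::mutate(auroc = runif(dplyr::n()), target_stays = 5000L)
  m <- collect_matched_scores(grid, "auroc", bin = "small")
  expect_equal(dim(m), c(3L, 12L))   # 4 pairs x 3 architectures
  m1 <- collect_matched_scores(grid, "auroc", bin = "small", arch = "cnn")
  expect_equal(dim(m1), c(3L, 4L))
  expect_error(collect_matched_scores(grid, "auroc", bin = "large"), "bin")
})
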