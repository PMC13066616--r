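#' Threshold-free classification metrics
#'
#' AUROC via the rank statistic with tie correction, AUPRC via step
#' integration of the precision-recall curve over distinct thresholds, the
#' prevalence-normalized AUPRC `nAUPRC = AUPRC / baseline` with
#' `baseline = positives / total` (1 = chance level), and recall at a fixed
#' score threshold.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) labels; both classes must be present.
#' @param threshold Score threshold for recall (default 0.5).
#' @return One-row tibble: `auroc`, `auprc`, `baseline`, `nauprc`, `recall`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("metrics require both classes to be present")
  }
  r <- rank(scores)
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  # group tied scores so each distinct threshold contributes one PR point
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)

  baseline <- n_pos / length(labels)
  tibble(
    auroc = auroc, auprc = auprc, baseline = baseline,
    nauprc = auprc / baseline,
    recall = sum(scores >= threshold & labels) / n_pos
  )
}

#' Prevalence as a printed percentage
#'
#' Sepsis-stay percentage from cohort counts, rounded to the conventional
#' three decimals (e.g. 5638 of 123413 stays is 4.568).
#'
#' @param n_sepsis,n_total Stay counts.
#' @param digits Decimal places (default 3).
#' @return Numeric percentage.
#' @export
prevalence_percent <- function(n_sepsis, n_total, digits = 3) {
  round(100 * n_sepsis / n_total, digits)
}

#' Per-stay summary statistics of raw dynamic features
#'
#' For each stay and feature: mean, variance (sample, n - 1), minimum, and
#' maximum over the *observed* values of the raw, pre-imputation table —
#' 4 x n_features summary columns (192 at the 48-feature default). A stay
#' with no observations of a feature contributes missing cells for all four
#' statistics; a single observation leaves the variance undefined.
#'
#' @param dynamic Raw dynamic table (`stay_id`, `hour`, features), missing
#'   values intact.
#' @param features Feature names (default: all non-key columns).
#' @return Tibble `stay_id` + `<feature>_<stat>` columns in feature-major
#'   order (`mean`, `var`, `min`, `max` per feature).
#' @export
per_stay_summaries <- function(dynamic, features = NULL) {
  if (is.null(features)) features <- setdiff(names(dynamic), c("stay_id", "hour"))
  safe_min <- function(v) if (length(v) == 0) NA_real_ else min(v)
  safe_max <- function(v) if (length(v) == 0) NA_real_ else max(v)
  safe_mean <- function(v) if (length(v) == 0) NA_real_ else mean(v)
  safe_var <- function(v) if (length(v) < 2) NA_real_ else var(v)
  out <- dynamic |>
    summarise(across(
      all_of(features),
      list(mean = ~ safe_mean(.x[!is.na(.x)]),
           var = ~ safe_var(.x[!is.na(.x)]),
           min = ~ safe_min(.x[!is.na(.x)]),
           max = ~ safe_max(.x[!is.na(.x)])),
      .names = "{.col}_{.fn}"
    ), .by = "stay_id") |>
    arrange(.data$stay_id)
  out
}

summary_cols <- function(summ) setdiff(names(summ), "stay_id")

#' Two-sample Kolmogorov-Smirnov shift tests with BH correction
#'
#' One two-sample K-S test per summary column, Benjamini-Hochberg adjusted
#' across all testable columns of the site pair; significance at adjusted
#' p < `alpha` (default 0.01). Columns with fewer than two non-missing
#' values on either side are flagged untestable and excluded from the BH
#' family.
#'
#' @param summ_a,summ_b Per-stay summary tables from [per_stay_summaries()]
#'   with identical summary columns.
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @return Tibble: `column`, `feature`, `statistic`, `ks_stat`, `p_value`,
#'   `p_adj`, `significant`, `testable`.
#' @export
ks_shift_test <- function(summ_a, summ_b, alpha = 0.01) {
  cols <- summary_cols(summ_a)
  stopifnot(identical(cols, summary_cols(summ_b)))
  res <- map(cols, function(cl) {
    a <- summ_a[[cl]]; a <- a[!is.na(a)]
    b <- summ_b[[cl]]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(column = cl, ks_stat = NA_real_, p_value = NA_real_,
                    testable = FALSE))
    }
    kt <- suppressWarnings(ks.test(a, b))
    tibble(column = cl, ks_stat = unname(kt$statistic),
           p_value = kt$p.value, testable = TRUE)
  }) |> list_rbind()
  if (any(!res$testable)) {
    message(sum(!res$testable), " summary column(s) untestable; excluded from the BH family")
  }
  res$p_adj <- NA_real_
  res$p_adj[res$testable] <- p.adjust(res$p_value[res$testable], method = "BH")
  res |>
    mutate(
      feature = sub("_(mean|var|min|max)$", "", .data$column),
      statistic = sub("^.*_(mean|var|min|max)$", "\\1", .data$column),
      significant = .data$testable & .data$p_adj < alpha
    ) |>
    select("column", "feature", "statistic", "ks_stat", "p_value", "p_adj",
           "significant", "testable")
}

#' Absolute Cohen's d per summary column
#'
#' `|mean_a - mean_b| / s_pooled` with the (n - 1)-weighted pooled standard
#' deviation, binned as negligible (< 0.2), small (0.2–0.5), medium
#' (0.5–0.8), or large (>= 0.8). A zero pooled SD leaves d undefined
#' (flagged `NA`).
#'
#' @inheritParams ks_shift_test
#' @return Tibble: `column`, `feature`, `statistic`, `cohens_d`,
#'   `effect_bin`.
#' @export
cohens_d <- function(summ_a, summ_b) {
  cols <- summary_cols(summ_a)
  stopifnot(identical(cols, summary_cols(summ_b)))
  d <- map_dbl(cols, function(cl) {
    a <- summ_a[[cl]]; a <- a[!is.na(a)]
    b <- summ_b[[cl]]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 <= 0) return(NA_real_)
    abs(mean(a) - mean(b)) / sqrt(sp2)
  })
  tibble(
    column = cols,
    feature = sub("_(mean|var|min|max)$", "", cols),
    statistic = sub("^.*_(mean|var|min|max)$", "\\1", cols),
    cohens_d = d,
    effect_bin = effect_size_bin(d)
  )
}

effect_size_bin <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE)
}

#' Full distribution-shift report for a site pair
#'
#' Combines K-S + BH significance and absolute Cohen's d over the
#' 4 x n_features per-stay summary columns, and counts the features that are
#' significantly shifted in all four statistics ("fully shifted") and those
#' with medium-or-large effect sizes.
#'
#' @param dynamic_a,dynamic_b Raw (pre-imputation) dynamic tables of the two
#'   sites.
#' @param features Feature names (default: common non-key columns).
#' @param alpha Significance level (default 0.01).
#' @return A `shift_report`: tibble of per-column results with count
#'   attributes; see [glance.shift_report()].
#' @export
shift_report <- function(dynamic_a, dynamic_b, features = NULL, alpha = 0.01) {
  if (is.null(features)) {
    features <- intersect(setdiff(names(dynamic_a), c("stay_id", "hour")),
                          setdiff(names(dynamic_b), c("stay_id", "hour")))
  }
  sa <- per_stay_summaries(dynamic_a, features)
  sb <- per_stay_summaries(dynamic_b, features)
  ks <- ks_shift_test(sa, sb, alpha = alpha)
  cd <- cohens_d(sa, sb)
  rep_ <- left_join(ks, cd |> select("column", "cohens_d", "effect_bin"),
                    by = "column")
  fully <- rep_ |>
    summarise(all_sig = all(.data$significant), .by = "feature") |>
    filter(.data$all_sig)
  med_large <- rep_ |>
    filter(.data$statistic == "mean",
           .data$effect_bin %in% c("medium", "large")) |>
    distinct(.data$feature)
  structure(rep_,
            class = c("shift_report", class(rep_)),
            n_features = length(features),
            fully_shifted = fully$feature,
            medium_or_large = med_large$feature,
            alpha = alpha)
}

#' @export
tidy.shift_report <- function(x, ...) as_tibble(x)

#' Shift-report headline counts
#'
#' @param x A `shift_report`.
#' @param ... Unused.
#' @return One-row tibble: number of summary columns, count of features
#'   significant in all four statistics, count with medium-or-large mean
#'   effect size.
#' @export
glance.shift_report <- function(x, ...) {
  tibble(
    n_features = attr(x, "n_features"),
    n_summary_columns = nrow(x),
    n_fully_shifted = length(attr(x, "fully_shifted")),
    n_medium_or_large = length(attr(x, "medium_or_large"))
  )
}

#' @export
autoplot.shift_report <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$cohens_d))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect_bin, fill = .data$statistic)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "absolute Cohen's d bin", y = "summary columns",
                  title = "Effect sizes of per-stay summary shifts") +
    ggplot2::theme_minimal()
}

#' Target-data size bin
#'
#' Stay-count regimes: small (up to 8000 stays), medium (8000 to 32000),
#' large (more than 32000).
#'
#' @param n_stays Non-negative stay counts (vectorized).
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
size_bin <- function(n_stays) {
  if (any(n_stays < 0)) abort("n_stays must be non-negative")
  cut(n_stays, breaks = c(-Inf, 8000, 32000, Inf),
      labels = c("small", "medium", "large"), right = TRUE)
}

#' Matched score vectors for strategy ranking
#'
#' Collects, per strategy, one score per matched run unit — a
#' (source, target, architecture) combination — averaging over the target
#' fractions that fall in the requested size bin. With 4 source-to-target
#' pairs and 3 architectures this yields the 12-entry matched vectors of the
#' all-models panels (4 with a single architecture).
#'
#' @param results Strategy-result rows (see [run_target_training()] etc.)
#'   with a `target_stays` column giving the target subset stay count.
#' @param metric `"auroc"` or `"nauprc"` (any result column).
#' @param bin `"small"`, `"medium"`, or `"large"`.
#' @param arch Optional single architecture to restrict to.
#' @return Matrix strategies x matched units.
#' @export
collect_matched_scores <- function(results, metric = "auroc",
                                   bin = "small", arch = NULL) {
  df <- results
  if (!is.null(arch)) df <- df |> filter(.data$arch == .env$arch)
  df <- df |>
    mutate(bin = size_bin(.data$target_stays)) |>
    filter(.data$bin == .env$bin)
  if (nrow(df) == 0) abort("no results fall in the requested bin")
  wide <- df |>
    summarise(score = mean(.data[[metric]]),
              .by = c("strategy", "source", "target", "arch")) |>
    mutate(unit = paste(.data$source, .data$target, .data$arch, sep = ">")) |>
    select("strategy", "unit", "score") |>
    tidyr::pivot_wider(names_from = "unit", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$strategy
  if (anyNA(m)) abort("matched score matrix has missing cells (unmatched runs)")
  m
}

#' Rank deployment strategies with paired Wilcoxon tests
#'
#' Means each strategy's matched score vector, assigns ordinal ranks
#' (1 = best; ties broken by full numeric precision, then by name), and runs
#' a two-sided paired Wilcoxon signed-rank test on every strategy pair
#' (zero differences dropped; exact null for n <= 25, normal approximation
#' above), Bonferroni-corrected over all pairs. Significance tiers at
#' adjusted p < 0.05 / 0.01 / 0.001.
#'
#' @param scores Matrix strategies x matched runs (identical run columns
#'   across strategies), e.g. from [collect_matched_scores()].
#' @param n_pairs Number of pairwise tests for the Bonferroni correction
#'   (default `choose(nrow(scores), 2)`).
#' @return A `rank_table`: list with `ranking` (strategy, mean score, rank)
#'   and `pairs` (pairwise p-values, adjusted p, tier).
#' @export
rank_strategies <- function(scores, n_pairs = NULL) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.null(rownames(scores))) {
    abort("scores must have strategy rownames")
  }
  k <- nrow(scores)
  if (k < 2) abort("ranking needs at least two strategies")
  if (is.null(n_pairs)) n_pairs <- choose(k, 2)
  means <- rowMeans(scores)
  ord <- order(-means, rownames(scores))
  ranking <- tibble(strategy = rownames(scores)[ord],
                    mean_score = means[ord],
                    rank = seq_len(k))
  combos <- utils::combn(rownames(scores), 2)
  pairs <- map(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    p <- paired_wilcoxon_p(scores[a, ], scores[b, ])
    tibble(strategy_a = a, strategy_b = b, p_value = p,
           p_adj = min(1, p * n_pairs))
  }) |> list_rbind()
  pairs$tier <- cut(pairs$p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", ""), right = FALSE)
  structure(list(ranking = ranking, pairs = pairs,
                 n_runs = ncol(scores), n_pairs = n_pairs),
            class = "rank_table")
}

# Two-sided paired Wilcoxon signed-rank p-value: zero differences dropped,
# exact distribution for n <= 25 (when |differences| are untied), normal
# approximation otherwise.
paired_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value
  )
}

#' @export
print.rank_table <- function(x, ...) {
  cat("<rank_table> ", nrow(x$ranking), " strategies over ", x$n_runs,
      " matched runs\n", sep = "")
  print(x$ranking)
  sig <- x$pairs |> filter(.data$tier != "")
  if (nrow(sig) > 0) {
    cat("significant pairs (Bonferroni over", x$n_pairs, "tests):\n")
    print(sig)
  }
  invisible(x)
}

#' @export
tidy.rank_table <- function(x, ...) x$ranking

#' @export
glance.rank_table <- function(x, ...) {
  tibble(n_strategies = nrow(x$ranking), n_runs = x$n_runs,
         n_pairs = x$n_pairs,
         n_significant = sum(x$pairs$tier != ""))
}

#' @export
autoplot.rank_table <- function(object, ...) {
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(x = stats::reorder(.data$strategy, .data$rank),
                               y = .data$mean_score)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean score",
                  title = "Deployment strategies, best to worst") +
    ggplot2::theme_minimal()
}
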