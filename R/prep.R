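#' Per-stay outcome flags from hourly labels
#'
#' @param labels Hourly label tibble (`stay_id`, `hour`, `label`).
#' @return Tibble `stay_id`, `septic` (any positive hour).
#' @export
stay_outcomes <- function(labels) {
  labels |>
    summarise(septic = any(.data$label), .by = "stay_id") |>
    arrange(.data$stay_id)
}

#' Temporal train/validation/test split with label-balance repair
#'
#' Stays are ordered by admission timestamp (ties broken by `stay_id`) and
#' assigned to contiguous temporal blocks — train, validation, test — of the
#' requested fractions (largest-remainder rounding). Because a purely
#' temporal cut can leave a split with an unrepresentative septic fraction,
#' boundary stays are then swapped minimally across block boundaries until
#' every split's septic fraction is within the tolerance of the cohort
#' fraction (stratification by stay and label). Deterministic.
#'
#' @param static Static table with `stay_id` and `admission_time`.
#' @param outcomes Per-stay outcomes (`stay_id`, `septic`), e.g. from
#'   [stay_outcomes()].
#' @param fractions Named fractions summing to 1 (default
#'   `c(train = 0.8, val = 0.1, test = 0.1)`).
#' @param tolerance Allowed absolute deviation of each split's septic
#'   fraction from the cohort fraction; a slack of one stay per split is
#'   always allowed (default 0.01).
#' @return Tibble `stay_id`, `split` (factor `train`/`val`/`test`).
#' @export
temporal_split <- function(static, outcomes,
                           fractions = c(train = 0.8, val = 0.1, test = 0.1),
                           tolerance = 0.01) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  df <- static |>
    select("stay_id", "admission_time") |>
    left_join(outcomes, by = "stay_id") |>
    arrange(.data$admission_time, .data$stay_id)
  if (anyNA(df$septic)) abort("every stay must have an outcome")
  n <- nrow(df)
  sizes <- largest_remainder(n, fractions)
  split <- rep(names(fractions), times = sizes)
  septic <- df$septic
  overall <- mean(septic)

  # minimal boundary swaps to restore label balance
  for (iter in seq_len(50L)) {
    dev <- map_dbl(names(fractions), function(s) {
      idx <- split == s
      mean(septic[idx]) - overall
    })
    names(dev) <- names(fractions)
    slack <- pmax(tolerance, 1 / sizes)
    bad <- which(abs(dev) > slack)
    if (length(bad) == 0) break
    worst <- bad[which.max(abs(dev[bad]))]
    s <- names(fractions)[worst]
    need_septic <- dev[worst] < 0
    # trade with the split at the other extreme of the imbalance, so two
    # deficient splits never steal the same stay from each other
    partner <- names(fractions)[if (need_septic) which.max(dev) else which.min(dev)]
    if (identical(partner, s)) break
    idx_s <- which(split == s)
    idx_o <- which(split == partner)
    give <- idx_s[septic[idx_s] != need_septic]
    take <- idx_o[septic[idx_o] == need_septic]
    if (length(give) == 0 || length(take) == 0) break
    # pick the pair closest to the split's boundary (minimal temporal damage)
    pick_take <- take[which.min(map_dbl(take, function(i) min(abs(i - range(idx_s)))))]
    pick_give <- give[which.min(abs(give - pick_take))]
    tmp <- split[pick_give]; split[pick_give] <- split[pick_take]; split[pick_take] <- tmp
  }
  tibble(stay_id = df$stay_id,
         split = factor(split, levels = names(fractions)))
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(left)]] <- sizes[order_rem[seq_len(left)]] + 1
  }
  as.integer(sizes)
}

#' Nested, label-stratified training subsets
#'
#' Draws subsets of the training stays at increasing fractions such that each
#' subset contains every stay of the smaller ones (the 10% subset is the 5%
#' subset plus 5% new stays, and so on), with the septic fraction of every
#' subset within one stay of the cohort fraction. Reproducible from `seed`.
#'
#' @param train_stays Stay ids of the training split.
#' @param outcomes Per-stay outcomes (`stay_id`, `septic`).
#' @param fractions Strictly increasing fractions ending at 1 (default
#'   `c(0.05, 0.10, 0.20, 0.50, 0.75, 1.0)`).
#' @param seed Integer seed for the subset draw.
#' @return Named list (fraction as name) of stay-id vectors, strictly nested.
#' @export
nested_subsets <- function(train_stays, outcomes,
                           fractions = c(0.05, 0.10, 0.20, 0.50, 0.75, 1.0),
                           seed = 1L) {
  if (any(diff(fractions) <= 0) || abs(tail(fractions, 1) - 1) > 1e-8) {
    abort("fractions must be strictly increasing and end at 1.0")
  }
  oc <- outcomes |> filter(.data$stay_id %in% train_stays)
  set.seed(seed)
  septic_ids <- sample(oc$stay_id[oc$septic])
  control_ids <- sample(oc$stay_id[!oc$septic])
  n <- length(septic_ids) + length(control_ids)
  out <- list()
  for (f in fractions) {
    n_f <- round(f * n)
    n_sep <- min(round(f * length(septic_ids)), n_f)
    # never draw an all-control subset of a cohort that has septic stays
    # (stratification tolerance is +/- one stay)
    if (length(septic_ids) > 0 && n_f > 0) n_sep <- max(1L, n_sep)
    ids <- c(head(septic_ids, n_sep), head(control_ids, n_f - n_sep))
    out[[format(f)]] <- sort(ids)
  }
  out
}

#' Training-set feature means
#'
#' Mean of each dynamic feature over observed (non-missing) values of the
#' training stays only; used to seed imputation where a stay has no prior
#' measurement.
#'
#' @param dynamic Raw dynamic table.
#' @param train_stays Stay ids of the training split.
#' @param features Feature names.
#' @return Named numeric vector of means.
#' @export
train_feature_means <- function(dynamic, train_stays, features) {
  sub <- dynamic |> filter(.data$stay_id %in% train_stays)
  means <- map_dbl(features, ~ mean(sub[[.x]], na.rm = TRUE))
  setNames(means, features)
}

#' Flag missingness and impute
#'
#' Adds one binary flag column per feature (`<feature>_missing`, 1 where the
#' original value was unobserved), then forward-fills each feature within a
#' stay with the last available measurement; leading runs with no prior value
#' are filled with the training-set mean of that feature. The output has no
#' missing cells.
#'
#' @param dynamic Dynamic table (`stay_id`, `hour`, features).
#' @param train_means Named vector of training-set means covering every
#'   feature (see [train_feature_means()]).
#' @param features Feature names (default: all train_means names).
#' @return Tibble with value columns imputed plus flag columns appended.
#' @export
flag_and_impute <- function(dynamic, train_means, features = names(train_means)) {
  missing_means <- setdiff(features, names(train_means))
  if (length(missing_means) > 0) {
    abort(paste("no training mean for feature(s):",
                paste(missing_means, collapse = ", ")),
          class = "sepshift_config_error")
  }
  dyn <- dynamic |> arrange(.data$stay_id, .data$hour)
  stay <- dyn$stay_id
  new_stay <- c(TRUE, stay[-1] != stay[-length(stay)])
  out <- dyn
  for (f in features) {
    v <- dyn[[f]]
    flag <- as.integer(is.na(v))
    v <- locf_by_stay(v, new_stay)
    v[is.na(v)] <- train_means[[f]]
    out[[f]] <- v
    out[[paste0(f, "_missing")]] <- flag
  }
  out
}

# last-observation-carried-forward that never crosses stay boundaries
locf_by_stay <- function(v, new_stay) {
  idx <- seq_along(v)
  stay_start <- cummax(ifelse(new_stay, idx, 0L))
  last_obs <- cummax(ifelse(is.na(v), 0L, idx))
  ok <- last_obs > 0L & last_obs >= stay_start
  out <- rep(NA_real_, length(v))
  out[ok] <- v[last_obs[ok]]
  out
}

#' Segment imputed data into fixed-length windows
#'
#' One window per (stay, end hour) with `end_hour >= length - 1`, sliding at
#' the given stride; the window label is the hourly label at the window's
#' last hour, so a positive window occurs up to six hours before onset.
#' Stays shorter than the window length yield no windows. Time and stay id
#' never enter the feature channels; they are kept as provenance.
#'
#' @param dynamic Imputed dynamic table with flag columns
#'   (from [flag_and_impute()]); must contain no missing values.
#' @param labels Hourly labels (`stay_id`, `hour`, `label`).
#' @param channels Channel columns (default: everything except `stay_id`,
#'   `hour`).
#' @param length Window length in hours (default 6).
#' @param stride Window stride in hours (default 1).
#' @return A `window_set`: list with `x` (array `n x length x channels`),
#'   `label` (logical), `provenance` (tibble `stay_id`, `end_hour`), and
#'   `channels`.
#' @export
make_windows <- function(dynamic, labels, channels = NULL,
                         length = 6L, stride = 1L) {
  if (is.null(channels)) channels <- setdiff(names(dynamic), c("stay_id", "hour"))
  dyn <- dynamic |> arrange(.data$stay_id, .data$hour)
  if (anyNA(dyn[channels])) abort("windows require imputed (complete) data")
  lab <- labels |> select("stay_id", "hour", "label")
  dyn <- dyn |> left_join(lab, by = c("stay_id", "hour"))
  mats <- split(as.data.frame(dyn[c(channels, "label")]), dyn$stay_id)
  L <- as.integer(length); stride <- as.integer(stride)

  xs <- list(); labs <- list(); prov <- list()
  for (sid in names(mats)) {
    m <- mats[[sid]]
    n_h <- nrow(m)
    if (n_h < L) next
    ends <- seq(L - 1L, n_h - 1L, by = stride)   # 0-based end hours
    vals <- as.matrix(m[channels])
    win <- array(0, dim = c(length(ends), L, length(channels)))
    for (j in seq_along(ends)) {
      rows <- (ends[j] - L + 2L):(ends[j] + 1L)   # hour h lives in row h+1
      win[j, , ] <- vals[rows, , drop = FALSE]
    }
    xs[[sid]] <- win
    labs[[sid]] <- m$label[ends + 1L]
    prov[[sid]] <- tibble(stay_id = as.integer(sid), end_hour = ends)
  }
  if (length(xs) == 0) {
    return(new_window_set(array(0, c(0, L, length(channels))),
                          logical(), tibble(stay_id = integer(), end_hour = integer()),
                          channels))
  }
  x <- abind_first(xs)
  new_window_set(x, unlist(labs, use.names = FALSE),
                 list_rbind(unname(prov)), channels)
}

new_window_set <- function(x, label, provenance, channels) {
  structure(list(x = x, label = as.logical(label), provenance = provenance,
                 channels = channels),
            class = "window_set")
}

abind_first <- function(lst) {
  d <- dim(lst[[1]])
  n <- sum(map_int(lst, ~ dim(.x)[1]))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in lst) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", n_windows(x), " windows x ", dim(x$x)[2], " h x ",
      dim(x$x)[3], " channels; ", sum(x$label), " positive\n", sep = "")
  invisible(x)
}

#' Number of windows in a window set
#' @param windows A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(windows) dim(windows$x)[1]

#' Subset a window set by stay
#' @param windows A `window_set`.
#' @param stay_ids Stays to keep.
#' @return A `window_set` restricted to those stays.
#' @export
filter_windows <- function(windows, stay_ids) {
  keep <- windows$provenance$stay_id %in% stay_ids
  new_window_set(windows$x[keep, , , drop = FALSE], windows$label[keep],
                 windows$provenance[keep, ], windows$channels)
}

#' Concatenate window sets
#' @param a,b `window_set` objects with identical channels.
#' @return A combined `window_set`.
#' @export
bind_windows <- function(a, b) {
  stopifnot(identical(a$channels, b$channels))
  new_window_set(abind_first(list(a$x, b$x)), c(a$label, b$label),
                 bind_rows(a$provenance, b$provenance), a$channels)
}

#' Fit a per-channel standardizer on training windows
#'
#' Learns per-channel mean and variance from the training windows only
#' (pooled over windows and hours). Degenerate (constant) channels get
#' variance 1 with a warning so scaling never divides by zero.
#'
#' @param windows Training `window_set`.
#' @return Tibble `channel`, `mean`, `var` of class `scaler_params`.
#' @export
fit_scaler <- function(windows) {
  if (n_windows(windows) == 0) abort("cannot fit a scaler on empty windows")
  C <- dim(windows$x)[3]
  flat <- matrix(windows$x, ncol = C)   # (n*T) x C, column-major over channels
  mu <- colMeans(flat)
  v <- apply(flat, 2, function(col) mean((col - mean(col))^2))
  degenerate <- v < 1e-12
  if (any(degenerate)) {
    warn(paste("constant channel(s), variance clamped to 1:",
               paste(windows$channels[degenerate], collapse = ", ")))
    v[degenerate] <- 1
  }
  structure(tibble(channel = windows$channels, mean = mu, var = v),
            class = c("scaler_params", "tbl_df", "tbl", "data.frame"))
}

#' Apply a fitted standardizer
#'
#' @param windows A `window_set`.
#' @param params `scaler_params` from [fit_scaler()] (learned on training
#'   windows; the same parameters are applied to validation and test sets).
#' @return The scaled `window_set`.
#' @export
apply_scaler <- function(windows, params) {
  stopifnot(identical(windows$channels, params$channel))
  x <- windows$x
  C <- dim(x)[3]
  for (c in seq_len(C)) {
    x[, , c] <- (x[, , c] - params$mean[c]) / sqrt(params$var[c])
  }
  out <- windows
  out$x <- x
  out$scaled <- TRUE
  out
}

#' Prepare one site end to end
#'
#' Labels the cohort, drops excluded stays, splits temporally, computes
#' training-set feature means, flags/imputes, and windows each split.
#' Windows are returned unscaled together with a scaler fitted on the
#' training windows, so deployment strategies can choose the normalization
#' that matches their training data (e.g. fusion refits on pooled data).
#'
#' @param cohort A `cohort_table`.
#' @param labelling Optional precomputed result of [label_cohort()].
#' @param fractions,tolerance Passed to [temporal_split()].
#' @param window_hours,stride Passed to [make_windows()].
#' @return List with `windows` (list `train`/`val`/`test`, unscaled),
#'   `scaler` (fit on train), `split`, `outcomes`, `labels`, `onsets`,
#'   `train_means`.
#' @export
prepare_site <- function(cohort, labelling = NULL,
                         fractions = c(train = 0.8, val = 0.1, test = 0.1),
                         tolerance = 0.01, window_hours = 6L, stride = 1L) {
  if (is.null(labelling)) labelling <- label_cohort(cohort)
  kept <- labelling$kept_stays
  static <- cohort$static |> filter(.data$stay_id %in% kept)
  dynamic <- cohort$dynamic |> filter(.data$stay_id %in% kept)
  outcomes <- stay_outcomes(labelling$labels)
  split <- temporal_split(static, outcomes, fractions, tolerance)
  train_ids <- split$stay_id[split$split == "train"]

  means <- train_feature_means(dynamic, train_ids, cohort$features)
  imputed <- flag_and_impute(dynamic, means, cohort$features)
  windows <- map(
    setNames(levels(split$split), levels(split$split)),
    function(s) {
      ids <- split$stay_id[split$split == s]
      make_windows(imputed |> filter(.data$stay_id %in% ids),
                   labelling$labels, length = window_hours, stride = stride)
    }
  )
  scaler <- fit_scaler(windows$train)
  list(windows = windows, scaler = scaler, split = split,
       outcomes = outcomes, labels = labelling$labels,
       onsets = labelling$onsets, train_means = means)
}
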