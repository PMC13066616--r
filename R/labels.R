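#' Detect suspicion of infection
#'
#' Strict Sepsis-3 suspicion: a body-fluid culture paired with a qualifying
#' antibiotic course. A course qualifies when it runs continuously for at
#' least `min_abx_hours` (72 h, i.e. three days). Culture and course are
#' paired when the culture is drawn within `culture_after_abx` hours after
#' the course starts, or the course starts within `abx_after_culture` hours
#' after the culture — the standard Sepsis-3 pairing convention. The
#' suspicion time is the earlier of the pair; only the earliest suspicion per
#' stay is kept.
#'
#' @param abx Antibiotic courses: `stay_id`, `start_hour`, `end_hour`.
#' @param cultures Culture draws: `stay_id`, `hour`.
#' @param min_abx_hours Minimum continuous course length (default 72).
#' @param culture_after_abx,abx_after_culture Pairing window halves in hours
#'   (defaults 24 and 72).
#' @return Tibble of suspicion events: `stay_id`, `suspicion_hour`,
#'   `culture_hour`, `abx_start_hour`, `abx_duration_h`; zero rows when no
#'   pair qualifies.
#' @export
detect_suspicion <- function(abx, cultures, min_abx_hours = 72,
                             culture_after_abx = 24, abx_after_culture = 72) {
  empty <- tibble(stay_id = integer(), suspicion_hour = integer(),
                  culture_hour = integer(), abx_start_hour = integer(),
                  abx_duration_h = integer())
  if (is.null(abx) || is.null(cultures) || nrow(abx) == 0 || nrow(cultures) == 0) {
    return(empty)
  }
  qual <- abx |>
    mutate(abx_duration_h = .data$end_hour - .data$start_hour) |>
    filter(.data$abx_duration_h >= min_abx_hours)
  if (nrow(qual) == 0) return(empty)

  pairs <- inner_join(
    qual |> select("stay_id", abx_start_hour = "start_hour", "abx_duration_h"),
    cultures |> select("stay_id", culture_hour = "hour"),
    by = "stay_id", relationship = "many-to-many"
  ) |>
    filter(
      (.data$culture_hour >= .data$abx_start_hour &
         .data$culture_hour <= .data$abx_start_hour + culture_after_abx) |
      (.data$abx_start_hour >= .data$culture_hour &
         .data$abx_start_hour <= .data$culture_hour + abx_after_culture)
    )
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    mutate(suspicion_hour = pmin(.data$culture_hour, .data$abx_start_hour)) |>
    slice_min(.data$suspicion_hour, n = 1, by = "stay_id", with_ties = FALSE) |>
    select("stay_id", "suspicion_hour", "culture_hour",
           "abx_start_hour", "abx_duration_h") |>
    arrange(.data$stay_id)
}

#' Confirm sepsis onset from the organ-dysfunction score
#'
#' For each suspicion event, searches the window
#' `[suspicion - window_before, suspicion + window_after]` (clipped to the
#' stay span) for the first hour whose organ score exceeds the minimum score
#' observed earlier in the window by at least `rise` (Sepsis-3: an acute rise
#' of 2 or more). Hours with no preceding in-window baseline cannot confirm
#' an onset.
#'
#' @param organ_score Hourly series: `stay_id`, `hour`, `score`.
#' @param suspicion Suspicion events from [detect_suspicion()].
#' @param window_before,window_after Search-window extent around the
#'   suspicion hour (defaults 48 and 24 h). Labels are sensitive to this
#'   choice; both halves are configurable.
#' @param rise Required score increase (default 2).
#' @return Tibble of onset records, one row per suspicion stay: `stay_id`,
#'   `onset_hour` (`NA` when no qualifying rise), `excluded` (all `FALSE`
#'   here), `exclusion_reason` (`"none"`).
#' @export
detect_onset <- function(organ_score, suspicion,
                         window_before = 48, window_after = 24, rise = 2) {
  if (nrow(suspicion) == 0) {
    return(tibble(stay_id = integer(), onset_hour = integer(),
                  excluded = logical(), exclusion_reason = character()))
  }
  missing_stays <- setdiff(suspicion$stay_id, unique(organ_score$stay_id))
  if (length(missing_stays) > 0) {
    abort(paste("no organ-score series for stay(s):",
                paste(head(missing_stays, 5), collapse = ", ")),
          class = "sepshift_key_error")
  }
  os <- organ_score |> arrange(.data$stay_id, .data$hour)
  os_by_stay <- split(os[c("hour", "score")], os$stay_id)
  onset_hour <- purrr::map2_int(
    suspicion$stay_id, suspicion$suspicion_hour,
    function(sid, sh) {
      sc <- os_by_stay[[as.character(sid)]]
      keep <- sc$hour >= sh - window_before & sc$hour <= sh + window_after
      sc <- sc[keep, , drop = FALSE]
      if (nrow(sc) < 2) return(NA_integer_)
      prior_min <- cummin(sc$score)
      delta <- sc$score[-1] - prior_min[-nrow(sc)]
      hit <- which(delta >= rise)
      if (length(hit) == 0) NA_integer_ else as.integer(sc$hour[hit[1] + 1L])
    }
  )
  tibble(stay_id = suspicion$stay_id, onset_hour = onset_hour,
         excluded = FALSE, exclusion_reason = "none")
}

#' Apply admission-window exclusions
#'
#' Stays whose onset falls before ICU admission are excluded as `pre_icu`;
#' stays developing sepsis within six hours of admission (onset hour 0..6)
#' are excluded as `within_6h`. Stays without an onset are kept as controls.
#'
#' @param onsets Onset records from [detect_onset()].
#' @param admission_hour Hour of admission on the stay grid (default 0).
#' @return The onset records with `excluded` / `exclusion_reason` filled in.
#' @export
apply_exclusions <- function(onsets, admission_hour = 0) {
  onsets |>
    mutate(
      exclusion_reason = case_when(
        is.na(.data$onset_hour) ~ "none",
        .data$onset_hour < admission_hour ~ "pre_icu",
        .data$onset_hour <= admission_hour + 6 ~ "within_6h",
        TRUE ~ "none"
      ),
      excluded = .data$exclusion_reason != "none"
    )
}

#' Build the hourly sepsis label series
#'
#' The label is set six hours before the confirmed onset and kept for at most
#' 13 hours after it: positives cover `max(0, onset - 6) .. min(onset + 13,
#' stay_end)` inclusive, a single contiguous block of at most 20 hours.
#' Stays without an onset are all-negative. Excluded stays must be removed
#' before calling.
#'
#' @param onsets Onset records (non-excluded) with `stay_id`, `onset_hour`.
#' @param spans Tibble `stay_id`, `span` (hours of data; grid `0..span-1`),
#'   e.g. from [stay_spans()].
#' @param lead_hours Hours of advance labeling before onset (default 6).
#' @param post_hours Maximum labeled hours after onset (default 13).
#' @return Tibble `stay_id`, `hour`, `label` (logical), one row per stay-hour.
#' @export
build_labels <- function(onsets, spans, lead_hours = 6, post_hours = 13) {
  if (any(onsets$excluded %||% FALSE)) {
    abort("excluded stays must be removed before building labels")
  }
  stopifnot(all(onsets$stay_id %in% spans$stay_id))
  df <- left_join(spans, onsets, by = "stay_id")
  rows <- pmap(list(df$stay_id, df$span, df$onset_hour), function(s, L, on) {
    hour <- 0:(L - 1L)
    lab <- if (is.na(on)) rep(FALSE, L) else
      hour >= max(0L, on - lead_hours) & hour <= min(on + post_hours, L - 1L)
    tibble(stay_id = s, hour = hour, label = lab)
  })
  list_rbind(rows)
}

#' Label a cohort end to end
#'
#' Runs suspicion detection, onset confirmation, admission-window exclusions,
#' and hourly label construction for a whole cohort. Excluded stays are
#' dropped from the label series (and should be dropped from any downstream
#' training cohort).
#'
#' @param cohort A `cohort_table`.
#' @inheritParams detect_suspicion
#' @inheritParams detect_onset
#' @inheritParams build_labels
#' @return List with `onsets` (every stay: `stay_id`, `onset_hour`,
#'   `excluded`, `exclusion_reason`), `labels` (hourly labels for kept
#'   stays), and `kept_stays` (stay ids surviving exclusion).
#' @export
label_cohort <- function(cohort, min_abx_hours = 72, culture_after_abx = 24,
                         abx_after_culture = 72, window_before = 48,
                         window_after = 24, rise = 2,
                         lead_hours = 6, post_hours = 13) {
  susp <- detect_suspicion(cohort$abx, cohort$cultures,
                           min_abx_hours = min_abx_hours,
                           culture_after_abx = culture_after_abx,
                           abx_after_culture = abx_after_culture)
  onsets <- detect_onset(cohort$organ_score, susp,
                         window_before = window_before,
                         window_after = window_after, rise = rise)
  all_onsets <- tibble(stay_id = cohort$static$stay_id) |>
    left_join(onsets, by = "stay_id") |>
    mutate(excluded = coalesce(.data$excluded, FALSE),
           exclusion_reason = coalesce(.data$exclusion_reason, "none")) |>
    apply_exclusions()
  kept <- all_onsets |> filter(!.data$excluded)
  spans <- stay_spans(cohort) |> filter(.data$stay_id %in% kept$stay_id)
  labels <- build_labels(kept, spans,
                         lead_hours = lead_hours, post_hours = post_hours)
  list(onsets = all_onsets, labels = labels, kept_stays = kept$stay_id)
}
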