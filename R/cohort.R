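#' Assemble a harmonized cohort bundle
#'
#' A cohort table is the package's universal exchange object for one site:
#' a static table (one row per ICU stay), an hourly dynamic table
#' (`stay_id` x `hour` x dynamic features, missing values allowed), and three
#' event tables consumed by Sepsis-3 labeling — antibiotic courses, body-fluid
#' culture draws, and an hourly organ-dysfunction score series.
#'
#' Conventions: the hourly grid is 0-based and relative to each stay
#' (hour 0 = admission), hours are contiguous integers, and the dynamic
#' horizon is at most 168 h (days 1–7 of the stay). `admission_time` in the
#' static table is the admission timestamp in hours since an arbitrary common
#' epoch; it orders stays for temporal splitting and does not shift the
#' per-stay hour grid.
#'
#' @param static Data frame with `stay_id`, `admission_time`, and at least the
#'   four demographic columns `age`, `sex`, `height`, `weight`.
#' @param dynamic Data frame with `stay_id`, `hour`, and one column per
#'   dynamic feature; `NA` marks unobserved values.
#' @param abx Data frame of antibiotic courses: `stay_id`, `start_hour`,
#'   `end_hour` (course may extend past the dynamic horizon).
#' @param cultures Data frame of culture draws: `stay_id`, `hour`.
#' @param organ_score Data frame with `stay_id`, `hour`, `score`
#'   (non-negative integer-like organ-dysfunction value).
#' @param features Character vector of dynamic feature names; defaults to the
#'   dynamic columns of `dynamic` in order.
#' @param meta Optional named list of metadata (site id, generator seed, ...).
#' @param validate Check invariants and abort on violations (default `TRUE`).
#'
#' @return An object of class `cohort_table`.
#' @seealso [validate_cohort()], [read_cohort()], [write_cohort()]
#' @export
cohort_table <- function(static, dynamic, abx = NULL, cultures = NULL,
                         organ_score = NULL, features = NULL, meta = list(),
                         validate = TRUE) {
  empty_events <- function(cols) {
    as_tibble(setNames(rep(list(integer()), length(cols)), cols))
  }
  static <- as_tibble(static)
  dynamic <- as_tibble(dynamic)
  abx <- if (is.null(abx)) empty_events(c("stay_id", "start_hour", "end_hour")) else as_tibble(abx)
  cultures <- if (is.null(cultures)) empty_events(c("stay_id", "hour")) else as_tibble(cultures)
  organ_score <- if (is.null(organ_score)) empty_events(c("stay_id", "hour", "score")) else as_tibble(organ_score)

  if (is.null(features)) {
    features <- setdiff(names(dynamic), c("stay_id", "hour"))
  }
  x <- structure(
    list(static = static, dynamic = dynamic, abx = abx, cultures = cultures,
         organ_score = organ_score, features = features, meta = meta),
    class = "cohort_table"
  )
  if (validate) {
    v <- validate_cohort(x)
    if (nrow(v) > 0) {
      abort(c("invalid cohort_table:",
              setNames(paste(v$table, v$rule, v$detail, sep = " | "),
                       rep("x", nrow(v)))),
            class = "sepshift_integrity_error")
    }
  }
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", n_stays(x), " stays, ", length(x$features),
      " dynamic features, ", nrow(x$dynamic), " stay-hours\n", sep = "")
  cat("  events: ", nrow(x$abx), " abx courses, ", nrow(x$cultures),
      " cultures, ", nrow(x$organ_score), " organ-score rows\n", sep = "")
  invisible(x)
}

#' Number of stays in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer count of stays.
#' @export
n_stays <- function(cohort) nrow(cohort$static)

#' Per-stay span (hours of dynamic data)
#'
#' @param cohort A `cohort_table`.
#' @return Tibble with `stay_id` and `span` (number of hourly rows; the grid
#'   covers hours `0 .. span - 1`).
#' @export
stay_spans <- function(cohort) {
  cohort$dynamic |>
    count(.data$stay_id, name = "span") |>
    arrange(.data$stay_id)
}

violation <- function(table, key, rule, detail) {
  tibble(table = table, key = as.character(key), rule = rule, detail = detail)
}

#' Check cohort invariants
#'
#' Pure validator: returns one row per violation rather than raising, so
#' callers can inspect everything that is wrong at once. Checked rules:
#' required columns; unique stay ids; non-negative integer hours on a
#' contiguous 0-based grid with no duplicate `(stay_id, hour)`; dynamic span
#' at most 168 h; every event/dynamic stay id present in the static table;
#' antibiotic `start_hour <= end_hour`; non-negative organ scores.
#'
#' @param cohort A `cohort_table`.
#' @return Tibble with columns `table`, `key`, `rule`, `detail`; zero rows iff
#'   all invariants hold.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  st <- cohort$static
  dyn <- cohort$dynamic

  need_static <- c("stay_id", "admission_time", sepshift_static_cols)
  miss <- setdiff(need_static, names(st))
  if (length(miss) > 0) {
    v[[length(v) + 1]] <- violation("static", NA, "missing_column",
                                    paste("missing:", paste(miss, collapse = ", ")))
  }
  need_dyn <- c("stay_id", "hour", cohort$features)
  miss <- setdiff(need_dyn, names(dyn))
  if (length(miss) > 0) {
    v[[length(v) + 1]] <- violation("dynamic", NA, "missing_column",
                                    paste("missing:", paste(miss, collapse = ", ")))
    return(list_rbind(v))
  }
  if ("stay_id" %in% names(st) && anyDuplicated(st$stay_id) > 0) {
    v[[length(v) + 1]] <- violation("static", NA, "duplicate_stay_id",
                                    "static stay_id not unique")
  }

  if (nrow(dyn) > 0) {
    if (any(dyn$hour < 0 | dyn$hour != floor(dyn$hour))) {
      v[[length(v) + 1]] <- violation("dynamic", NA, "hour_grid",
                                      "hours must be non-negative integers")
    }
    dup <- dyn |> count(.data$stay_id, .data$hour) |> filter(.data$n > 1)
    for (i in seq_len(nrow(dup))) {
      v[[length(v) + 1]] <- violation("dynamic", dup$stay_id[i], "duplicate_hour",
                                      paste0("duplicate (stay_id, hour): hour ", dup$hour[i]))
    }
    grid <- dyn |>
      summarise(n = n(), h_min = min(.data$hour), h_max = max(.data$hour),
                .by = "stay_id")
    bad_grid <- grid |>
      filter(.data$h_min != 0 | .data$h_max != .data$n - 1)
    # duplicate hours already reported; only flag stays whose hour set is not
    # a contiguous 0-based run once duplicates are accounted for
    bad_grid <- anti_join(bad_grid, dup, by = "stay_id")
    for (i in seq_len(nrow(bad_grid))) {
      v[[length(v) + 1]] <- violation("dynamic", bad_grid$stay_id[i], "irregular_grid",
                                      "hours are not a contiguous 0-based run")
    }
    too_long <- grid |> filter(.data$h_max >= SEPSHIFT_MAX_HOURS)
    for (i in seq_len(nrow(too_long))) {
      v[[length(v) + 1]] <- violation("dynamic", too_long$stay_id[i], "horizon",
                                      paste0("hour ", too_long$h_max[i],
                                             " exceeds the 168 h day-1..7 horizon"))
    }
    unknown <- setdiff(unique(dyn$stay_id), st$stay_id)
    if (length(unknown) > 0) {
      v[[length(v) + 1]] <- violation("dynamic", unknown[1], "unknown_stay",
                                      paste(length(unknown), "dynamic stay id(s) not in static"))
    }
  }

  check_events <- function(tab, name, hour_cols) {
    miss <- setdiff(c("stay_id", hour_cols), names(tab))
    if (length(miss) > 0) {
      v[[length(v) + 1]] <<- violation(name, NA, "missing_column",
                                       paste("missing:", paste(miss, collapse = ", ")))
      return(invisible(NULL))
    }
    if (nrow(tab) == 0) return(invisible(NULL))
    unknown <- setdiff(unique(tab$stay_id), st$stay_id)
    if (length(unknown) > 0) {
      v[[length(v) + 1]] <<- violation(name, unknown[1], "unknown_stay",
                                       paste(length(unknown), "stay id(s) not in static"))
    }
    for (hc in hour_cols) {
      if (any(tab[[hc]] < 0)) {
        v[[length(v) + 1]] <<- violation(name, NA, "negative_hour",
                                         paste0(hc, " must be >= 0"))
      }
    }
  }
  check_events(cohort$abx, "abx", c("start_hour", "end_hour"))
  check_events(cohort$cultures, "cultures", "hour")
  check_events(cohort$organ_score, "organ_score", "hour")

  if (all(c("start_hour", "end_hour") %in% names(cohort$abx)) && nrow(cohort$abx) > 0) {
    bad <- cohort$abx |> filter(.data$start_hour > .data$end_hour)
    for (i in seq_len(nrow(bad))) {
      v[[length(v) + 1]] <- violation("abx", bad$stay_id[i], "course_order",
                                      paste0("start ", bad$start_hour[i], " > end ", bad$end_hour[i]))
    }
  }
  if ("score" %in% names(cohort$organ_score) && nrow(cohort$organ_score) > 0) {
    if (any(cohort$organ_score$score < 0)) {
      v[[length(v) + 1]] <- violation("organ_score", NA, "negative_score",
                                      "organ-dysfunction score must be >= 0")
    }
  }
  if (length(v) == 0) return(violation(character(), character(), character(), character())[0, ])
  list_rbind(v)
}

cohort_files <- c(static = "static.csv", dynamic = "dynamic.csv",
                  abx = "abx.csv", cultures = "cultures.csv",
                  organ_score = "organ_score.csv")

#' Write a cohort bundle to disk
#'
#' Writes the five component tables plus a `manifest.yaml` recording the
#' feature list and metadata. Two dialects share one logical schema: `"csv"`
#' (normative; missing values as empty cells) and `"parquet"` (columnar
#' binary, requires the arrow package). `read_cohort(write_cohort(x))`
#' reproduces `x` exactly, including the missingness mask.
#'
#' @param cohort A valid `cohort_table`.
#' @param path Directory to create/write into.
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE)) {
    abort("the parquet dialect requires the 'arrow' package")
  }
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste("cannot create directory:", path), class = "sepshift_io_error")
  }
  ext <- if (format == "csv") ".csv" else ".parquet"
  for (tab in names(cohort_files)) {
    file <- file.path(path, sub("\\.csv$", ext, cohort_files[[tab]]))
    if (format == "csv") {
      readr::write_csv(cohort[[tab]], file, na = "")
    } else {
      arrow::write_parquet(cohort[[tab]], file)
    }
  }
  manifest <- list(
    schema = "sepshift-cohort-v1",
    format = format,
    features = as.list(cohort$features),
    meta = cohort$meta
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Read a cohort bundle from disk
#'
#' Reads a bundle written by [write_cohort()] (or assembled by hand to the
#' same schema) and validates all invariants.
#'
#' @param path Bundle directory containing `manifest.yaml` and the tables.
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path) {
  mf_path <- file.path(path, "manifest.yaml")
  if (!file.exists(mf_path)) {
    abort(paste("no manifest.yaml under", path), class = "sepshift_schema_error")
  }
  manifest <- yaml::read_yaml(mf_path)
  format <- manifest$format %||% "csv"
  features <- unlist(manifest$features)
  ext <- if (format == "csv") ".csv" else ".parquet"

  # CSV is parsed with base read.csv: its strtod-based parser is correctly
  # rounded, so the write/read cycle reproduces doubles bit-exactly
  read_tab <- function(tab, col_classes = NA) {
    file <- file.path(path, sub("\\.csv$", ext, cohort_files[[tab]]))
    if (!file.exists(file)) {
      abort(paste("bundle is missing", basename(file)), class = "sepshift_schema_error")
    }
    if (format == "csv") {
      # malformed bundles surface as schema errors below, not parser warnings
      out <- as_tibble(suppressWarnings(
        utils::read.csv(file, na.strings = "", colClasses = col_classes,
                        check.names = FALSE)
      ))
    } else {
      out <- as_tibble(arrow::read_parquet(file))
    }
    out
  }
  static <- read_tab("static", c(stay_id = "integer"))
  dyn_classes <- c(stay_id = "integer", hour = "integer",
                   setNames(rep("numeric", length(features)), features))
  dynamic <- read_tab("dynamic", dyn_classes)
  for (col in c("stay_id", "hour", features)) {
    if (!col %in% names(dynamic)) {
      abort(paste0("dynamic table lacks required column '", col, "'"),
            class = "sepshift_schema_error")
    }
  }
  abx <- read_tab("abx", "integer")
  cultures <- read_tab("cultures", "integer")
  organ_score <- read_tab("organ_score", "integer")

  cohort_table(static, dynamic, abx, cultures, organ_score,
               features = features, meta = manifest$meta %||% list(),
               validate = TRUE)
}
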