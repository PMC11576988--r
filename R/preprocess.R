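#' @title Preprocessing filters for raw trial records
#'
#' @description Cleaning rules applied to trial-level records before fitting:
#' removal of implausibly fast or slow responses (signs of cheating or
#' disengagement), removal of participants who completed the same task at
#' more than one timepoint (to avoid learning curves), and removal of span
#' trials longer than a plausibility cap (a sign of writing the sequence
#' down). Each filter returns the retained records together with a
#' `filter_report` accounting for every removed record; filters are
#' idempotent and commute.
#'
#' @param records data.frame of trial records (columns as in
#'   [task_dataset()]; `rt` in milliseconds).
#' @name preprocessing
NULL

new_filter_report <- function(n_input, n_removed_fast = 0L, n_removed_slow = 0L,
                              n_participants_dropped_repeat = 0L,
                              n_removed_repeat = 0L, n_removed_span_cap = 0L,
                              thresholds = list()) {
  structure(
    list(
      n_input = as.integer(n_input),
      n_removed_fast = as.integer(n_removed_fast),
      n_removed_slow = as.integer(n_removed_slow),
      n_participants_dropped_repeat = as.integer(n_participants_dropped_repeat),
      n_removed_repeat = as.integer(n_removed_repeat),
      n_removed_span_cap = as.integer(n_removed_span_cap),
      n_output = as.integer(n_input - n_removed_fast - n_removed_slow -
                              n_removed_repeat - n_removed_span_cap),
      thresholds = thresholds
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "records in,", x$n_output, "retained\n")
  cat("  fast-RT removed:     ", x$n_removed_fast, "\n")
  cat("  slow-RT removed:     ", x$n_removed_slow, "\n")
  cat("  repeat participants: ", x$n_participants_dropped_repeat,
      "(", x$n_removed_repeat, "records )\n")
  cat("  span-cap removed:    ", x$n_removed_span_cap, "\n")
  invisible(x)
}

check_nonempty <- function(records, stage) {
  if (nrow(records) == 0L) {
    stop("all records removed by ", stage, ": empty task", call. = FALSE)
  }
  records
}

#' Remove reaction-time outliers
#'
#' Retains records with `low_ms <= rt <= high_ms`. Responses outside the
#' window are signs of either cheating (too fast) or not engaging with the
#' task (too slow). Thresholds are task-specific and should come from
#' inspection of the task's RT distribution; the shipped defaults are
#' deliberately wide.
#'
#' @inheritParams preprocessing
#' @param low_ms,high_ms retention window in milliseconds (`low_ms < high_ms`).
#' @return list with `records` (retained rows) and `report`
#'   (a `filter_report`).
#' @export
filter_rt_outliers <- function(records, low_ms = 200, high_ms = 60000) {
  stopifnot(low_ms < high_ms)
  records <- as.data.frame(records)
  fast <- records$rt < low_ms
  slow <- records$rt > high_ms
  out <- records[!fast & !slow, , drop = FALSE]
  report <- new_filter_report(
    n_input = nrow(records),
    n_removed_fast = sum(fast), n_removed_slow = sum(slow),
    thresholds = list(rt_low_ms = low_ms, rt_high_ms = high_ms)
  )
  list(records = check_nonempty(out, "RT outlier filter"), report = report)
}

#' Drop participants seen at multiple timepoints
#'
#' Removes all records of any participant observed at more than one
#' timepoint for this task, preventing learning effects from repeat
#' assessment contaminating the difficulty and ability estimates.
#'
#' @inheritParams preprocessing
#' @return list with `records` and `report`.
#' @export
drop_repeat_participants <- function(records) {
  records <- as.data.frame(records)
  if (is.null(records$timepoint)) stop("records lack a timepoint column")
  ntp <- tapply(records$timepoint, records$participant_id,
                function(x) length(unique(x)))
  repeaters <- names(ntp)[ntp > 1L]
  keep <- !(records$participant_id %in% repeaters)
  out <- records[keep, , drop = FALSE]
  report <- new_filter_report(
    n_input = nrow(records),
    n_participants_dropped_repeat = length(repeaters),
    n_removed_repeat = sum(!keep)
  )
  list(records = check_nonempty(out, "repeat-participant filter"),
       report = report)
}

#' Cap span-task trial length
#'
#' For span tasks whose trial label encodes the numeric sequence length,
#' removes records with a length above `max_len`; sequences beyond the cap
#' (10 for spatial span, 11 for digit span) indicate participants writing
#' the sequence down.
#'
#' @inheritParams preprocessing
#' @param max_len maximum admissible span length.
#' @return list with `records` and `report`.
#' @export
cap_span_trials <- function(records, max_len) {
  records <- as.data.frame(records)
  span <- suppressWarnings(as.numeric(records$trial_label))
  if (anyNA(span)) {
    stop("trial_label must encode a numeric span length in span mode",
         call. = FALSE)
  }
  keep <- span <= max_len
  out <- records[keep, , drop = FALSE]
  report <- new_filter_report(
    n_input = nrow(records), n_removed_span_cap = sum(!keep),
    thresholds = list(span_cap = max_len)
  )
  list(records = check_nonempty(out, "span cap"), report = report)
}

#' Compose trial labels from raw design columns
#'
#' The difficulty dimension is task-specific (a word, a start/end
#' configuration, a distance bin, a span length, a moves-drops pair, ...).
#' This concatenates the named raw columns into a single `trial_label` key,
#' deterministically, with `"_"` as separator.
#'
#' @param raw data.frame of raw records.
#' @param label_spec character vector of column names composing the label.
#' @param sep separator between fields.
#' @return `raw` with a `trial_label` column prepended/replaced.
#' @export
build_trial_labels <- function(raw, label_spec, sep = "_") {
  raw <- as.data.frame(raw)
  missing_cols <- setdiff(label_spec, names(raw))
  if (length(missing_cols) > 0L) {
    stop("label_spec names absent column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parts <- lapply(raw[label_spec], as.character)
  raw$trial_label <- do.call(paste, c(parts, sep = sep))
  raw
}

#' Bin a continuous difficulty dimension into labels
#'
#' For tasks whose difficulty dimension is continuous (e.g. distance from
#' the previous target), bins the values into `n_bins` equal-width bins and
#' uses the bin index as the trial label.
#'
#' @param x numeric vector of the raw difficulty dimension.
#' @param n_bins number of equal-width bins (default 20).
#' @return character vector of bin labels (`"01"`, `"02"`, ...), ordered by
#'   the underlying value.
#' @export
bin_difficulty_dimension <- function(x, n_bins = 20) {
  stopifnot(n_bins >= 1, is.numeric(x))
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(sprintf("%02d", 1L), length(x)))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  sprintf("%02d", idx)
}
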