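#' Trial-level task dataset
#'
#' Bundles the retained trial records of one cognitive task with its scoring
#' mode and the global reaction-time scaling constant `rt_max`. A record is
#' one presentation of a trial to a participant: the trial's label (the
#' task's difficulty-dimension descriptor, e.g. a word, a span length or a
#' moves-drops combination), the reaction time in milliseconds, the response
#' score, the presentation order within the participant and the study
#' timepoint.
#'
#' @param records data.frame with columns `participant_id`, `trial_label`,
#'   `rt` (milliseconds, strictly positive), `correct` (logical; binary mode)
#'   or `acc` (numeric in \[0,1\]; continuous mode), and optionally `order`
#'   (presentation index within participant; defaults to row order) and
#'   `timepoint` (defaults to 1).
#' @param mode `"binary"` (scored by the correctness indicator) or
#'   `"continuous"` (scored by a graded accuracy in \[0,1\]). Exactly one of
#'   the two score columns governs scoring; graded scores outside \[0,1\]
#'   (e.g. a 3/2/1/0 rubric) must be normalised first, see
#'   [normalize_graded_accuracy()].
#' @param rt_max reaction-time scaling constant in ms. Defaults to the
#'   maximum `rt` over all retained records, the convention used throughout;
#'   it may be supplied explicitly (e.g. to score a subsample on the full
#'   sample's scale) but must be at least `max(rt)`.
#'
#' @return An object of class `task_dataset`: a list with elements `records`,
#'   `mode`, `rt_max` and `at_max` (`NA` until an ability stage has been run).
#' @seealso [read_trials_csv()], [idoct()]
#' @export
task_dataset <- function(records, mode = c("binary", "continuous"),
                         rt_max = NULL) {
  mode <- match.arg(mode)
  records <- as.data.frame(records)
  required <- c("participant_id", "trial_label", "rt")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("records is empty", call. = FALSE)

  records$participant_id <- as.character(records$participant_id)
  records$trial_label <- as.character(records$trial_label)
  records$rt <- as.numeric(records$rt)
  if (anyNA(records$rt) || any(records$rt <= 0)) {
    stop("rt must be strictly positive and non-missing", call. = FALSE)
  }

  if (mode == "binary") {
    if (is.null(records$correct)) {
      stop("binary mode requires a 'correct' column", call. = FALSE)
    }
    records$correct <- as.logical(records$correct)
    if (anyNA(records$correct)) stop("correct contains NA", call. = FALSE)
  } else {
    if (is.null(records$acc)) {
      stop("continuous mode requires an 'acc' column", call. = FALSE)
    }
    records$acc <- as.numeric(records$acc)
    if (anyNA(records$acc) || any(records$acc < 0 | records$acc > 1)) {
      stop("acc must lie in [0, 1] with no NA; normalise graded scores first",
           call. = FALSE)
    }
  }

  if (is.null(records$order)) {
    # fall back to file/row order within participant
    records$order <- stats::ave(seq_len(nrow(records)),
                                records$participant_id, FUN = seq_along)
  }
  records$order <- as.integer(records$order)
  dup <- stats::ave(records$order, records$participant_id,
                    FUN = function(x) as.integer(anyDuplicated(x) > 0L))
  if (any(dup == 1L)) {
    stop("presentation order must be unique within each participant",
         call. = FALSE)
  }
  if (is.null(records$timepoint)) records$timepoint <- 1L
  records$timepoint <- as.integer(records$timepoint)

  observed_max <- max(records$rt)
  if (is.null(rt_max)) {
    rt_max <- observed_max
  } else if (rt_max < observed_max) {
    stop("rt_max (", rt_max, ") is below the maximum observed rt (",
         observed_max, "): scaling-constant inconsistency", call. = FALSE)
  }

  structure(
    list(records = records, mode = mode, rt_max = rt_max, at_max = NA_real_),
    class = "task_dataset"
  )
}

#' @export
print.task_dataset <- function(x, ...) {
  r <- x$records
  cat("task_dataset (", x$mode, " accuracy)\n", sep = "")
  cat("  records:      ", nrow(r), "\n", sep = "")
  cat("  participants: ", length(unique(r$participant_id)), "\n", sep = "")
  cat("  trial labels: ", length(unique(r$trial_label)), "\n", sep = "")
  cat("  rt_max:       ", format(x$rt_max), " ms\n", sep = "")
  invisible(x)
}

# per-record score in [0,1]: correctness indicator or graded accuracy
trial_score <- function(dataset) {
  if (dataset$mode == "binary") {
    as.numeric(dataset$records$correct)
  } else {
    dataset$records$acc
  }
}

#' Normalise graded accuracy scores onto \[0, 1\]
#'
#' Maps an ordinal rubric (e.g. the 3/2/1/0 object-recognition scoring where
#' 3 = item, pose and orientation all correct) linearly onto \[0, 1\] so it
#' can serve as the continuous accuracy.
#'
#' @param score numeric vector of raw graded scores.
#' @param max_score maximum attainable score; defaults to `max(score)`.
#' @param min_score score mapped to 0 (default 0).
#' @return numeric vector in \[0, 1\].
#' @export
normalize_graded_accuracy <- function(score, max_score = max(score),
                                      min_score = 0) {
  if (max_score <= min_score) stop("max_score must exceed min_score")
  pmin(1, pmax(0, (score - min_score) / (max_score - min_score)))
}

#' Read trial-level records from CSV
#'
#' Expects a header with columns `participant_id`, `trial_label` (or raw
#' label fields composed via `label_spec`), `rt_ms`, `correct` or `acc`, and
#' optionally `order` and `timepoint`. Row order is used as the presentation
#' order when `order` is absent.
#'
#' @param path CSV file path.
#' @param mode scoring mode, `"binary"` or `"continuous"`.
#' @param label_spec optional character vector of raw column names whose
#'   values are concatenated into `trial_label` (see [build_trial_labels()]).
#' @param rt_max optional explicit scaling constant (ms).
#' @return A [task_dataset()].
#' @export
read_trials_csv <- function(path, mode = c("binary", "continuous"),
                            label_spec = NULL, rt_max = NULL) {
  mode <- match.arg(mode)
  # read everything as character so label keys keep leading zeros; the
  # dataset constructor handles the numeric conversions
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(label_spec)) raw <- build_trial_labels(raw, label_spec)
  if (!"rt_ms" %in% names(raw)) {
    stop("CSV is missing mandatory column: rt_ms", call. = FALSE)
  }
  raw$rt <- raw$rt_ms
  task_dataset(raw, mode = mode, rt_max = rt_max)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trials_csv()]: writes `participant_id`, `trial_label`,
#' `rt_ms`, the score column for the dataset's mode, `order` and `timepoint`.
#'
#' @param dataset a [task_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(dataset, path) {
  r <- dataset$records
  score_col <- if (dataset$mode == "binary") "correct" else "acc"
  out <- data.frame(
    participant_id = r$participant_id,
    trial_label = r$trial_label,
    rt_ms = r$rt,
    score = r[[score_col]],
    order = r$order,
    timepoint = r$timepoint
  )
  names(out)[names(out) == "score"] <- score_col
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
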