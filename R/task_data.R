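# Data model and I/O for the 2IFC Vernier task.
#
# One trial = two successive intervals, both containing a Vernier stimulus.
# Only the offset-present (OP) interval carries a left/right offset; the
# offset-absent (OA) interval shows a neutral, aligned Vernier. Participants
# report the offset orientation in both intervals and then pick the interval
# in which the offset was more visible.

TASKS <- c("masked", "unmasked")
ORIENTATIONS <- c("left", "right")
INTERVALS <- c("first", "second")

TRIAL_COLUMNS <- c(
  "participant_id", "task", "level_index", "level_value",
  "offset_orientation", "op_interval",
  "resp_orientation_op", "resp_orientation_oa", "resp_interval",
  "session", "block"
)

#' Condition levels for one task
#'
#' The masked task manipulates the inter-stimulus interval (ISI) between the
#' Vernier and a metacontrast mask: six levels, linearly spaced from 16.7 to
#' 100 ms. The unmasked task manipulates presentation duration on a
#' tachistoscope: eight levels, logarithmically spaced from 980 to 3000
#' microseconds. Levels are indexed 1-based with index 1 the hardest
#' (shortest ISI / briefest duration).
#'
#' @param task `"masked"` or `"unmasked"`.
#' @return Data frame with columns `task`, `index`, `physical_value`
#'   (ms for masked, microseconds for unmasked).
#' @export
condition_levels <- function(task = c("masked", "unmasked")) {
  task <- match.arg(task)
  if (task == "masked") {
    data.frame(task = task, index = 1:6,
               physical_value = seq(16.7, 100, length.out = 6))
  } else {
    data.frame(task = task, index = 1:8,
               physical_value = exp(seq(log(980), log(3000), length.out = 8)))
  }
}

#' Scale level values to (0, 1]
#'
#' Visibility levels are divided by the largest level value before entering
#' any regression, so the level covariate lies in (0, 1].
#'
#' @param values Numeric vector of physical level values.
#' @return Numeric vector scaled by `max(values)`.
#' @export
scale_levels <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("level values must be positive and finite", call. = FALSE)
  }
  values / max(values)
}

validate_trials <- function(df) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty dataset: no trial rows", call. = FALSE)
  check_enum <- function(col, domain) {
    bad <- which(!(df[[col]] %in% domain))
    if (length(bad) > 0L) {
      stop(sprintf("invalid value '%s' in column '%s' at row %d",
                   df[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
  }
  check_enum("task", TASKS)
  check_enum("offset_orientation", ORIENTATIONS)
  check_enum("op_interval", INTERVALS)
  check_enum("resp_orientation_op", ORIENTATIONS)
  check_enum("resp_orientation_oa", ORIENTATIONS)
  check_enum("resp_interval", INTERVALS)
  for (col in c("level_index", "level_value", "session", "block")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  df$participant_id <- as.character(df$participant_id)
  # Derived correctness flags are computed on load, never stored in files.
  df$ori_correct <- df$resp_orientation_op == df$offset_orientation
  df$int_correct <- df$resp_interval == df$op_interval
  class(df) <- c("trial_records", "data.frame")
  df
}

#' Load trial records from CSV
#'
#' Reads a headered CSV with one row per trial (columns `participant_id`,
#' `task`, `level_index`, `level_value`, `offset_orientation`, `op_interval`,
#' `resp_orientation_op`, `resp_orientation_oa`, `resp_interval`, `session`,
#' `block`), validates every row, and computes the derived correctness flags
#' `ori_correct` (OP-interval orientation response matches the true offset
#' orientation) and `int_correct` (interval choice matches the OP interval).
#'
#' @param path Path to a CSV file.
#' @param task_filter Optional task (`"masked"` or `"unmasked"`) to retain.
#' @return A `trial_records` data frame, row order preserved.
#' @export
load_trials <- function(path, task_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- validate_trials(df)
  if (!is.null(task_filter)) {
    task_filter <- match.arg(task_filter, TASKS)
    df <- df[df$task == task_filter, , drop = FALSE]
    if (nrow(df) == 0L) stop("empty dataset after task filter", call. = FALSE)
    class(df) <- c("trial_records", "data.frame")
  }
  df
}

#' Write trial records to CSV
#'
#' Derived correctness flags are dropped so files never carry redundant
#' (possibly inconsistent) state.
#'
#' @param trials A `trial_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, TRIAL_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

single_task <- function(trials) {
  tk <- unique(trials$task)
  if (length(tk) != 1L) {
    stop("trials mix tasks: ", paste(tk, collapse = ", "), call. = FALSE)
  }
  tk
}

#' Collapse trials to per-level joint outcome counts
#'
#' Data are collapsed across offset orientation, interval presentation order
#' and session into one summary per participant x level. The four joint
#' counts cross orientation correctness with interval correctness: `n11`
#' (both correct), `n10` (orientation only), `n01` (interval only), `n00`
#' (neither). The same five counts are also carried restricted to trials
#' with the offset in the first and in the second interval (suffixes
#' `_first`, `_second`); these feed the interval-order analyses.
#'
#' @param trials A `trial_records` data frame; all rows must share one task.
#' @return A `level_summaries` data frame.
#' @export
collapse_to_level_summaries <- function(trials) {
  tk <- single_task(trials)
  key <- interaction(trials$participant_id, trials$level_index, drop = TRUE)
  cell <- function(sub) {
    counts <- function(idx) {
      o <- sub$ori_correct[idx]; i <- sub$int_correct[idx]
      c(n = length(idx),
        n11 = sum(o & i), n10 = sum(o & !i),
        n01 = sum(!o & i), n00 = sum(!o & !i))
    }
    all_idx <- seq_len(nrow(sub))
    first <- which(sub$op_interval == "first")
    second <- which(sub$op_interval == "second")
    c(counts(all_idx),
      stats::setNames(counts(first), paste0(names(counts(first)), "_first")),
      stats::setNames(counts(second), paste0(names(counts(second)), "_second")))
  }
  parts <- split(seq_len(nrow(trials)), key)
  rows <- lapply(parts, function(idx) {
    sub <- trials[idx, , drop = FALSE]
    data.frame(participant_id = sub$participant_id[1],
               task = tk,
               level_index = sub$level_index[1],
               level_value = sub$level_value[1],
               t(cell(sub)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$level_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("level_summaries", "data.frame")
  out
}

#' Screen participants by performance slopes
#'
#' For each participant, fits a logistic regression of correctness on scaled
#' level — once for orientation discrimination and once for OP-interval
#' selection — and computes a Bayes factor contrasting a positive slope
#' (half-Gaussian prior, sd 2.30, upper tail) against a null slope (point
#' prior at 0). A participant is excluded when either Bayes factor is <= 1/3,
#' i.e. when performance does not increase with stimulus visibility.
#'
#' @param trials A `trial_records` data frame of one task.
#' @return Data frame with columns `participant_id`, `task`,
#'   `bf_orientation_slope`, `bf_interval_slope`, `excluded`,
#'   `trigger_orientation`, `trigger_interval`.
#' @export
screen_participants <- function(trials) {
  tk <- single_task(trials)
  xs <- scale_levels(condition_levels(tk)$physical_value)
  rows <- lapply(split(trials, trials$participant_id), function(sub) {
    levs <- sort(unique(sub$level_index))
    if (length(levs) < 2L) {
      stop("participant ", sub$participant_id[1],
           " has a single level of data; slope undefined", call. = FALSE)
    }
    per_level <- function(flag) {
      k <- tapply(flag, sub$level_index, sum)
      n <- tapply(flag, sub$level_index, length)
      list(k = as.numeric(k), n = as.numeric(n),
           x = xs[as.numeric(names(k))])
    }
    po <- per_level(sub$ori_correct)
    pi_ <- per_level(sub$int_correct)
    bf_o <- slope_bf(po$k, po$n, po$x)$bf10
    bf_i <- slope_bf(pi_$k, pi_$n, pi_$x)$bf10
    data.frame(participant_id = sub$participant_id[1], task = tk,
               bf_orientation_slope = bf_o, bf_interval_slope = bf_i,
               excluded = (bf_o <= 1 / 3) || (bf_i <= 1 / 3),
               trigger_orientation = bf_o <= 1 / 3,
               trigger_interval = bf_i <= 1 / 3)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
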