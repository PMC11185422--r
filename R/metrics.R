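# Descriptive behavioral metrics: per-level accuracies, Type-2 hit and
# false-alarm rates, discrimination conditional on the interval choice,
# interval-position splits, and group-level response biases.

metric_series <- function(name, per_participant) {
  # per_participant: data.frame(participant_id, level_index, value) where
  # value may be NA for undefined cells (zero denominators).
  defined <- per_participant[!is.na(per_participant$value), , drop = FALSE]
  grp <- do.call(rbind, c(list(data.frame(level_index = numeric(0),
                                          mean = numeric(0),
                                          sem = numeric(0),
                                          n_participants = numeric(0))),
    lapply(split(defined, defined$level_index), function(sub) {
      data.frame(level_index = sub$level_index[1],
                 mean = mean(sub$value),
                 sem = if (nrow(sub) > 1)
                   stats::sd(sub$value) / sqrt(nrow(sub)) else NA_real_,
                 n_participants = nrow(sub))
    })))
  rownames(grp) <- NULL
  structure(list(metric_name = name,
                 per_participant = per_participant,
                 group = grp,
                 n_dropped = sum(is.na(per_participant$value))),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat("Metric:", x$metric_name, "\n")
  print(x$group)
  if (x$n_dropped > 0) cat(x$n_dropped, "undefined cell(s) dropped\n")
  invisible(x)
}

ratio_series <- function(name, summaries, num, den) {
  value <- ifelse(den > 0, num / den, NA_real_)
  metric_series(name, data.frame(
    participant_id = summaries$participant_id,
    level_index = summaries$level_index,
    value = value))
}

#' Accuracy by difficulty level
#'
#' Orientation accuracy is `(n11 + n10) / n`; interval (OP-selection)
#' accuracy is `(n11 + n01) / n`, per participant per level. The group mean
#' is the unweighted mean across participants and the SEM uses the sample
#' (n-1) standard deviation; undefined cells (n = 0) are dropped.
#'
#' @param summaries A `level_summaries` data frame.
#' @param which `"orientation"` or `"interval"`.
#' @return A `metric_series`.
#' @export
accuracy_by_level <- function(summaries, which = c("orientation", "interval")) {
  which <- match.arg(which)
  if (nrow(summaries) == 0L) stop("empty summaries", call. = FALSE)
  num <- if (which == "orientation") summaries$n11 + summaries$n10
         else summaries$n11 + summaries$n01
  ratio_series(paste0(which, "_accuracy"), summaries, num, summaries$n)
}

#' Type-2 hit and false-alarm rates
#'
#' A Type-2 hit is choosing the OP interval on an orientation-correct trial;
#' a Type-2 false alarm is choosing it on an orientation-incorrect trial.
#' `HR = n11 / (n11 + n10)`, `FAR = n01 / (n01 + n00)`. Cells with a zero
#' denominator (e.g. a perfect discriminator has no incorrect trials) are
#' flagged undefined and dropped from group means.
#'
#' @param summaries A `level_summaries` data frame.
#' @return List with `hr` and `far`, both `metric_series`.
#' @export
type2_rates <- function(summaries) {
  if (nrow(summaries) == 0L) stop("empty summaries", call. = FALSE)
  list(
    hr = ratio_series("type2_hit_rate", summaries,
                      summaries$n11, summaries$n11 + summaries$n10),
    far = ratio_series("type2_false_alarm_rate", summaries,
                       summaries$n01, summaries$n01 + summaries$n00)
  )
}

#' Orientation accuracy conditional on the interval choice
#'
#' Accuracy given the OP interval was chosen is `n11 / (n11 + n01)`; given
#' the OA interval was chosen it is `n10 / (n10 + n00)`.
#'
#' @param summaries A `level_summaries` data frame.
#' @return List with `given_op_chosen` and `given_oa_chosen` `metric_series`.
#' @export
conditional_accuracy <- function(summaries) {
  if (nrow(summaries) == 0L) stop("empty summaries", call. = FALSE)
  list(
    given_op_chosen = ratio_series("accuracy_given_op_chosen", summaries,
                                   summaries$n11,
                                   summaries$n11 + summaries$n01),
    given_oa_chosen = ratio_series("accuracy_given_oa_chosen", summaries,
                                   summaries$n10,
                                   summaries$n10 + summaries$n00)
  )
}

#' Split summaries by OP-interval position
#'
#' Returns the positional sub-summaries (offset shown in the first vs the
#' second interval) as standalone `level_summaries`, suitable for the same
#' metric operations and the interval-order Bayes-factor analysis.
#'
#' @param summaries A `level_summaries` data frame.
#' @return List with elements `op_first` and `op_second`.
#' @export
split_by_op_position <- function(summaries) {
  pick <- function(suffix) {
    out <- summaries[, c("participant_id", "task", "level_index",
                         "level_value"), drop = FALSE]
    for (col in c("n", "n11", "n10", "n01", "n00")) {
      out[[col]] <- summaries[[paste0(col, "_", suffix)]]
    }
    # A positional split is homogeneous in position by construction.
    for (col in c("n", "n11", "n10", "n01", "n00")) {
      out[[paste0(col, "_first")]] <-
        if (suffix == "first") out[[col]] else 0
      out[[paste0(col, "_second")]] <-
        if (suffix == "second") out[[col]] else 0
    }
    class(out) <- c("level_summaries", "data.frame")
    out
  }
  list(op_first = pick("first"), op_second = pick("second"))
}

#' Group-level response biases
#'
#' For each participant, the proportion of "left" orientation responses in
#' the OP interval and of "first" interval responses, in percent. Each is
#' tested against 50% with a one-sample two-tailed t test. Optionally an
#' intercept-only hierarchical logistic model is fitted and a Bayes factor
#' computed contrasting H0 (point prior at 0.5) with H1 (Normal(0.5, 0.025),
#' two-tailed) on the population-level response probability.
#'
#' @param trials A `trial_records` data frame of one task.
#' @param bf Compute the hierarchical-model Bayes factors (runs MCMC).
#' @param mcmc List of sampler settings passed to [fit_hier_logistic()]
#'   (`chains`, `iter`, `seed`).
#' @return List with components `orientation` and `interval`, each holding
#'   `per_participant` (percent), `mean`, `sd`, `t` (one-sample test), and
#'   optionally `bf` (a `bf_result`).
#' @export
response_bias <- function(trials, bf = FALSE,
                          mcmc = list(chains = 2, iter = 2000, seed = 1)) {
  single_task(trials)
  parts <- split(trials, trials$participant_id)
  if (length(parts) < 2L) stop("t undefined: need >= 2 participants",
                               call. = FALSE)
  one <- function(flag_fun, label) {
    pct <- vapply(parts, function(sub) 100 * mean(flag_fun(sub)), numeric(1))
    res <- list(per_participant = pct,
                mean = mean(pct), sd = stats::sd(pct),
                t = one_sample_t(pct, mu = 50))
    if (bf) {
      dat <- do.call(rbind, lapply(names(parts), function(p) {
        data.frame(participant = p,
                   level = 0,
                   k = sum(flag_fun(parts[[p]])),
                   n = nrow(parts[[p]]))
      }))
      fit <- fit_hier_logistic(dat,
        spec = logistic_model_spec(include_slope = FALSE, prior_a_bar_sd = 1),
        chains = mcmc$chains %||% 2, iter = mcmc$iter %||% 2000,
        seed = mcmc$seed %||% 1)
      pp <- posterior_predict(fit, 0)
      res$bf <- bayes_factor(pp$mean, pp$sd,
        h0 = prior_spec("point", center = 0.5),
        h1 = prior_spec("normal", center = 0.5, sd = 0.025))
    }
    res
  }
  list(
    orientation = one(function(s) s$resp_orientation_op == "left",
                      "p_left"),
    interval = one(function(s) s$resp_interval == "first", "p_first")
  )
}

#' Write a metric series to a tidy CSV
#'
#' One row per participant x level plus `GROUP` rows with the mean and SEM.
#'
#' @param series A `metric_series` or a list of them.
#' @param task Task label for the output.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(series, task, path) {
  if (inherits(series, "metric_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    pp <- data.frame(metric = s$metric_name, task = task,
                     level_index = s$per_participant$level_index,
                     participant = s$per_participant$participant_id,
                     value = s$per_participant$value, sem = NA_real_)
    gr <- data.frame(metric = s$metric_name, task = task,
                     level_index = s$group$level_index,
                     participant = "GROUP",
                     value = s$group$mean, sem = s$group$sem)
    rbind(pp, gr)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
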