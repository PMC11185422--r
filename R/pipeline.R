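# End-to-end orchestration: load or generate trials, screen participants,
# compute behavioral metrics, run the Bayes-factor analyses, fit observers,
# and write all tables plus a run manifest with content hashes.

#' Pipeline configuration
#'
#' @param input_csv Path to a trial CSV, or `NULL` to generate synthetic
#'   data from `truth`.
#' @param truth A [ground_truth()] (or list of them, one per task) used
#'   when `input_csv` is `NULL`.
#' @param tasks Tasks to analyze.
#' @param exclusion_policy `"per_task"` (screen and exclude within each
#'   task) or `"cross_task"` (a participant excluded in one task is removed
#'   from both).
#' @param models Observer model ids to fit.
#' @param n_sim Prediction-table trials per cell.
#' @param mcmc List of sampler settings: `chains`, `iter`.
#' @param cv List of cross-validation settings: `folds`, `resamples`.
#' @param run_bf Run the MCMC-based Bayes-factor analyses.
#' @param run_fits Fit the observer models.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_csv = NULL, truth = NULL,
                            tasks = "masked",
                            exclusion_policy = c("per_task", "cross_task"),
                            models = 3, n_sim = 1e4,
                            mcmc = list(chains = 2, iter = 2000),
                            cv = list(folds = 10, resamples = 5),
                            run_bf = TRUE, run_fits = TRUE,
                            seed = 1, out_dir = tempfile("vernier2ifc_")) {
  exclusion_policy <- match.arg(exclusion_policy)
  if (is.null(input_csv) && is.null(truth)) {
    truth <- lapply(tasks, function(tk) ground_truth(task = tk, seed = seed))
    names(truth) <- tasks
  }
  if (inherits(truth, "ground_truth")) {
    truth <- stats::setNames(list(truth), truth$task)
    tasks <- names(truth)
  }
  stopifnot(n_sim > 0)
  structure(list(input_csv = input_csv, truth = truth, tasks = tasks,
                 exclusion_policy = exclusion_policy, models = models,
                 n_sim = n_sim, mcmc = mcmc, cv = cv, run_bf = run_bf,
                 run_fits = run_fits, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: input (load CSV or generate synthetic data), participant
#' screening and exclusion, behavioral metric tables, Bayes-factor analyses
#' (above-chance orientation and interval performance per level), observer
#' fitting (ideal and noisy per participant and model), and a JSON manifest
#' listing every output file with an MD5 content hash, the seeds, package
#' version and stage timings. A given config + seed is reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest and in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  outputs <- character(0)
  timings <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  clock <- function(name, expr) {
    st <- Sys.time()
    out <- pipeline_stage(name, expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    out
  }

  trials_by_task <- clock("input", {
    if (!is.null(config$input_csv)) {
      all_trials <- load_trials(config$input_csv)
      out <- lapply(config$tasks, function(tk) {
        sub <- all_trials[all_trials$task == tk, , drop = FALSE]
        class(sub) <- c("trial_records", "data.frame")
        sub
      })
      names(out) <- config$tasks
      out
    } else {
      out <- lapply(names(config$truth), function(tk) {
        tr <- generate_dataset(config$truth[[tk]],
                               seed = derive_seed(config$seed, match(tk, names(config$truth))))
        emit(tr[, TRIAL_COLUMNS], paste0("trials_", tk, ".csv"))
        tr
      })
      names(out) <- names(config$truth)
      out
    }
  })

  screening <- clock("screening", {
    reports <- lapply(trials_by_task, screen_participants)
    excl <- do.call(rbind, reports)
    emit(excl, "exclusions.csv")
    if (config$exclusion_policy == "cross_task") {
      bad <- unique(excl$participant_id[excl$excluded])
      trials_by_task <- lapply(trials_by_task, function(tr) {
        keep <- tr[!(tr$participant_id %in% bad), , drop = FALSE]
        class(keep) <- c("trial_records", "data.frame")
        keep
      })
    } else {
      kept <- lapply(names(trials_by_task), function(tk) {
        bad <- excl$participant_id[excl$excluded & excl$task == tk]
        keep <- trials_by_task[[tk]][
          !(trials_by_task[[tk]]$participant_id %in% bad), , drop = FALSE]
        class(keep) <- c("trial_records", "data.frame")
        keep
      })
      names(kept) <- names(trials_by_task)
      trials_by_task <- kept
    }
    excl
  })

  metrics <- clock("metrics", {
    lapply(names(trials_by_task), function(tk) {
      tr <- trials_by_task[[tk]]
      summ <- collapse_to_level_summaries(tr)
      t2 <- type2_rates(summ)
      cond <- conditional_accuracy(summ)
      series <- list(accuracy_by_level(summ, "orientation"),
                     accuracy_by_level(summ, "interval"),
                     t2$hr, t2$far,
                     cond$given_op_chosen, cond$given_oa_chosen)
      write_metric_table(series, tk,
                         file.path(config$out_dir,
                                   paste0("metrics_", tk, ".csv")))
      outputs <<- c(outputs, file.path(config$out_dir,
                                       paste0("metrics_", tk, ".csv")))
      bias <- response_bias(tr)
      emit(data.frame(
        task = tk,
        measure = c("p_left", "p_first"),
        mean_pct = c(bias$orientation$mean, bias$interval$mean),
        sd_pct = c(bias$orientation$sd, bias$interval$sd),
        t = c(bias$orientation$t$t, bias$interval$t$t),
        df = c(bias$orientation$t$df, bias$interval$t$df),
        p = c(bias$orientation$t$p, bias$interval$t$p)),
        paste0("bias_", tk, ".csv"))
      summ
    })
  })

  if (config$run_bf) {
    clock("bayes_factors", {
      for (tk in names(trials_by_task)) {
        tr <- trials_by_task[[tk]]
        bf_tabs <- lapply(c("orientation", "interval"), function(w) {
          an <- analyze_above_chance(
            tr, w, chains = config$mcmc$chains %||% 2,
            iter = config$mcmc$iter %||% 2000,
            seed = derive_seed(config$seed, 11 + match(w, c("orientation",
                                                            "interval"))))
          cbind(analysis = paste0("above_chance_", w), task = tk, an$bf)
        })
        emit(do.call(rbind, bf_tabs), paste0("bf_", tk, ".csv"))
      }
    })
  }

  if (config$run_fits) {
    clock("observer_fits", {
      for (tk in names(trials_by_task)) {
        tr <- trials_by_task[[tk]]
        rows <- list()
        for (m in config$models) {
          spec <- observer_spec(m)
          table <- simulate_prediction_table(
            spec, n_sim = config$n_sim,
            seed = derive_seed(config$seed, 100 + m))
          for (pid in unique(tr$participant_id)) {
            sub <- tr[tr$participant_id == pid, , drop = FALSE]
            class(sub) <- c("trial_records", "data.frame")
            for (variant in c("ideal", "noisy")) {
              f <- fit_observer(sub, spec, variant, table = table,
                                seed = config$seed, cv = TRUE,
                                folds = config$cv$folds %||% 10,
                                resamples = config$cv$resamples %||% 5)
              rows[[length(rows) + 1]] <- data.frame(
                task = tk, participant = pid, model_id = m,
                variant = variant,
                c_hat = paste(signif(f$c_hat, 4), collapse = ";"),
                sigma_d_hat = f$sigma_d_hat, logL = f$logL, bic = f$bic,
                cv_logl_mean = f$cv$mean, cv_logl_sem = f$cv$sem)
            }
          }
        }
        emit(do.call(rbind, rows), paste0("fits_", tk, ".csv"))
      }
    })
  }

  manifest <- list(
    package = "vernier2ifc",
    version = as.character(utils::packageVersion("vernier2ifc")),
    seed = config$seed,
    exclusion_policy = config$exclusion_policy,
    tasks = names(trials_by_task),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 out_dir = config$out_dir, screening = screening,
                 summaries = metrics))
}
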