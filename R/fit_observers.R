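# Fitting observers to behavioral data. Evidence strengths (one per
# difficulty level, nondecreasing toward easier levels) are fitted on the
# discrete simulated c grid by maximizing the multinomial likelihood of
# correct/incorrect orientation counts; the monotone constraint is solved
# exactly by dynamic programming over the grid. sigma_D is then fitted by
# grid search on the joint four-outcome likelihood. Model comparison uses
# BIC and 10-fold cross-validated log-likelihood with resampled splits.

PROB_FLOOR <- 1e-6

#' Parametric percent-correct preprocessing
#'
#' Fits a two-parameter logistic psychometric function of scaled level to
#' one participant's per-level orientation-correct counts (maximum
#' likelihood) and returns the fitted accuracy at each level, floored at
#' 0.5: the observers are only defined for accuracies between 0.5 and 1.
#' Complete separation is handled by add-0.5 count smoothing (flagged via
#' the `penalized` attribute).
#'
#' @param k Correct counts per level (hardest first).
#' @param n Trial counts per level.
#' @param x Scaled level values in (0, 1].
#' @return Numeric vector of fitted accuracies in `[0.5, 1]`, with
#'   attribute `penalized`.
#' @export
parametric_percent_correct <- function(k, n, x) {
  if (length(x) < 2L) stop("need >= 2 levels", call. = FALSE)
  penalized <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial()),
    warning = function(w) {
      penalized <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (penalized || abs(stats::coef(fit)[2]) > 15) {
    penalized <- TRUE
    fit <- suppressWarnings(
      stats::glm(cbind(k + 0.5, n - k + 0.5) ~ x,
                 family = stats::binomial()))
  }
  out <- pmax(0.5, as.numeric(stats::fitted(fit)))
  attr(out, "penalized") <- penalized
  out
}

#' Fit per-level evidence strengths under a monotonicity constraint
#'
#' Finds the grid values `c_hat` (one per level, nondecreasing from hardest
#' to easiest) maximizing the binomial likelihood
#' `prod_l P(correct|c_l)^k_l (1 - P(correct|c_l))^(n_l - k_l)`, where
#' `P(correct|c)` is the observer's simulated orientation accuracy. The
#' constrained discrete optimum is found exactly by dynamic programming
#' over the grid (prefix-max recursion); ties take the smaller c.
#'
#' @param table A `prediction_table` covering the c grid (any sigma; the
#'   orientation marginal is sigma-invariant).
#' @param k,n Correct and total effective counts per level, hardest first.
#' @return Numeric vector `c_hat`, one value per level, nondecreasing.
#' @export
fit_evidence_strengths <- function(table, k, n) {
  stopifnot(length(k) == length(n))
  p_ori <- pmin(pmax(pt_ori_correct(table), PROB_FLOOR), 1 - PROB_FLOOR)
  G <- length(p_ori)
  L <- length(k)
  score <- vapply(seq_len(L), function(l) {
    k[l] * log(p_ori) + (n[l] - k[l]) * log(1 - p_ori)
  }, numeric(G))  # G x L
  best <- matrix(-Inf, G, L)
  choice <- matrix(NA_integer_, G, L)
  best[, 1] <- score[, 1]
  for (l in seq_len(L)[-1]) {
    # prefix max of previous column: best value using grid index <= j
    pm <- numeric(G)
    pm_idx <- integer(G)
    run_best <- -Inf; run_idx <- NA_integer_
    for (j in seq_len(G)) {
      if (best[j, l - 1] > run_best) { run_best <- best[j, l - 1]; run_idx <- j }
      pm[j] <- run_best
      pm_idx[j] <- run_idx
    }
    best[, l] <- score[, l] + pm
    choice[, l] <- pm_idx
  }
  jj <- which.max(best[, L])  # which.max takes the first (smaller c) on ties
  idx <- integer(L)
  idx[L] <- jj
  for (l in rev(seq_len(L - 1))) {
    idx[l] <- choice[idx[l + 1], l + 1]
  }
  table$c_values[idx]
}

#' Joint multinomial log-likelihood of level summaries under an observer
#'
#' Sums `count * log P` over levels and the four joint outcomes
#' (orientation correct x interval correct) at the given per-level evidence
#' strengths and sigma_D. Probabilities are floored at 1e-6 before logging.
#'
#' @param table A `prediction_table`.
#' @param c_hat Per-level evidence strengths on the table's c grid,
#'   hardest first.
#' @param sigma_d A sigma value on the table's sigma grid.
#' @param counts Matrix or data frame with columns `n11`, `n10`, `n01`,
#'   `n00`, one row per level in the same order as `c_hat`.
#' @return Log-likelihood (scalar).
#' @export
joint_log_likelihood <- function(table, c_hat, sigma_d, counts) {
  if (nrow(counts) != length(c_hat)) {
    stop("counts and c_hat cover different numbers of levels", call. = FALSE)
  }
  ll <- 0
  for (l in seq_along(c_hat)) {
    p <- pmax(pt_cell(table, c_hat[l], sigma_d), PROB_FLOOR)
    nvec <- as.numeric(counts[l, c("n11", "n10", "n01", "n00")])
    ll <- ll + sum(nvec * log(p))
  }
  ll
}

#' Fit sigma_D by grid search
#'
#' Maximizes [joint_log_likelihood()] over the table's sigma grid with
#' `c_hat` held fixed; ties take the smaller sigma.
#'
#' @inheritParams joint_log_likelihood
#' @return List with `sigma_d_hat` and `logL`.
#' @export
fit_sigma_d <- function(table, c_hat, counts) {
  lls <- vapply(table$sigma_values, function(s)
    joint_log_likelihood(table, c_hat, s, counts), numeric(1))
  i <- which.max(lls)
  list(sigma_d_hat = table$sigma_values[i], logL = lls[i])
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 logL + k log(n_total)`, with `k` the number of fitted
#' parameters (one evidence strength per level, plus one when sigma_D is
#' free) and `n_total` the total number of trials.
#'
#' @param logL Maximized log-likelihood.
#' @param k Parameter count.
#' @param n_total Total number of data points.
#' @return Scalar BIC.
#' @export
bic <- function(logL, k, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  -2 * logL + k * log(n_total)
}

# Fold assignment balanced per level: within each level, trials are dealt
# round-robin after shuffling, so per-level counts across folds differ by
# at most one. Uses the current RNG.
assign_folds <- function(level_index, folds) {
  fold_of <- integer(length(level_index))
  for (li in unique(level_index)) {
    idx <- which(level_index == li)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_of
}

trial_counts_by_level <- function(trials, level_indices) {
  do.call(rbind, lapply(level_indices, function(li) {
    sub <- trials[trials$level_index == li, , drop = FALSE]
    o <- sub$ori_correct; i <- sub$int_correct
    data.frame(level_index = li, n = nrow(sub),
               n11 = sum(o & i), n10 = sum(o & !i),
               n01 = sum(!o & i), n00 = sum(!o & !i))
  }))
}

#' Cross-validated log-likelihood of a noisy observer
#'
#' Trials are split into `folds` subsets balanced per level (per-level
#' counts across folds differ by at most one). For each held-out fold,
#' sigma_D is refitted on the remaining folds (with `c_hat` held fixed at
#' the full-data estimate) and the held-out log-likelihood computed. The
#' per-resample score combines the fold likelihoods as the log of their
#' mean, `log(sum_i L_i / N)`, evaluated in log space via log-sum-exp;
#' `combine = "mean_log"` instead averages the fold log-likelihoods. The
#' whole procedure is repeated `resamples` times with fresh splits and the
#' scores averaged. For an ideal observer (sigma_D clamped at 0) there is
#' nothing to refit and the score equals the full-data log-likelihood.
#'
#' @param table A `prediction_table`.
#' @param c_hat Full-data per-level evidence strengths, hardest first.
#' @param trials One participant's `trial_records` for one task.
#' @param variant `"noisy"` or `"ideal"`.
#' @param folds,resamples Cross-validation settings.
#' @param seed Integer seed (splits are reproducible).
#' @param combine `"log_mean_lik"` (default) or `"mean_log"`.
#' @return List with `mean`, `sem`, `scores` (per resample).
#' @export
cv_logl <- function(table, c_hat, trials, variant = c("noisy", "ideal"),
                    folds = 10, resamples = 50, seed = 1,
                    combine = c("log_mean_lik", "mean_log")) {
  variant <- match.arg(variant)
  combine <- match.arg(combine)
  level_indices <- sort(unique(trials$level_index))
  if (variant == "ideal") {
    counts <- trial_counts_by_level(trials, level_indices)
    full <- joint_log_likelihood(table, c_hat, 0, counts)
    return(list(mean = full, sem = 0, scores = full))
  }
  scores <- withr::with_seed(derive_seed(seed, 7), {
    vapply(seq_len(resamples), function(r) {
      fold_of <- assign_folds(trials$level_index, folds)
      fold_ll <- vapply(seq_len(folds), function(f) {
        train <- trial_counts_by_level(trials[fold_of != f, , drop = FALSE],
                                       level_indices)
        test <- trial_counts_by_level(trials[fold_of == f, , drop = FALSE],
                                      level_indices)
        s_hat <- fit_sigma_d(table, c_hat, train)$sigma_d_hat
        joint_log_likelihood(table, c_hat, s_hat, test)
      }, numeric(1))
      if (combine == "log_mean_lik") {
        m <- max(fold_ll)
        m + log(mean(exp(fold_ll - m)))
      } else {
        mean(fold_ll)
      }
    }, numeric(1))
  })
  list(mean = mean(scores),
       sem = if (resamples > 1) stats::sd(scores) / sqrt(resamples) else 0,
       scores = scores)
}

#' Fit one observer to one participant's data
#'
#' Runs the full fitting pipeline: parametric percent-correct
#' preprocessing, conversion to effective counts (`round(n * accuracy)`
#' correct, remainder incorrect), monotone evidence-strength fitting on the
#' sigma = 0 slice, optional sigma_D grid fitting, joint log-likelihood,
#' BIC, and cross-validated log-likelihood.
#'
#' @param trials One participant's `trial_records` for one task.
#' @param spec An [observer_spec()].
#' @param variant `"ideal"` (sigma_D = 0) or `"noisy"` (sigma_D free).
#' @param table Optional precomputed `prediction_table` (reused across
#'   participants); simulated if `NULL`.
#' @param n_sim Trials per cell when simulating the table.
#' @param seed Seed for table simulation and CV splits.
#' @param cv Compute the cross-validated score.
#' @param folds,resamples CV settings.
#' @return An `observer_fit` list: `spec`, `variant`, `c_hat`,
#'   `sigma_d_hat`, `logL`, `bic`, `k`, `n_total`, `cv` (or `NULL`),
#'   `percent_correct`.
#' @export
fit_observer <- function(trials, spec, variant = c("ideal", "noisy"),
                         table = NULL, n_sim = 1e4, seed = 1, cv = TRUE,
                         folds = 10, resamples = 50) {
  variant <- match.arg(variant)
  if (is.null(table)) {
    table <- simulate_prediction_table(spec, n_sim = n_sim, seed = seed)
  }
  level_indices <- sort(unique(trials$level_index))
  counts <- trial_counts_by_level(trials, level_indices)
  xs <- scale_levels(condition_levels(single_task(trials))$physical_value)
  acc <- parametric_percent_correct(counts$n11 + counts$n10, counts$n,
                                    xs[level_indices])
  k_eff <- round(counts$n * acc)
  c_hat <- fit_evidence_strengths(table, k_eff, counts$n)
  if (variant == "ideal") {
    sigma_d_hat <- 0
    logL <- joint_log_likelihood(table, c_hat, 0, counts)
    k_par <- length(c_hat)
  } else {
    sf <- fit_sigma_d(table, c_hat, counts)
    sigma_d_hat <- sf$sigma_d_hat
    logL <- sf$logL
    k_par <- length(c_hat) + 1
  }
  n_total <- sum(counts$n)
  cv_res <- NULL
  if (cv) {
    cv_res <- cv_logl(table, c_hat, trials, variant = variant,
                      folds = folds, resamples = resamples, seed = seed)
  }
  structure(list(spec = spec, variant = variant, c_hat = c_hat,
                 sigma_d_hat = sigma_d_hat, logL = logL,
                 bic = bic(logL, k_par, n_total), k = k_par,
                 n_total = n_total, cv = cv_res,
                 percent_correct = as.numeric(acc),
                 level_indices = level_indices),
            class = "observer_fit")
}

EASY_LEVELS <- list(masked = c(5, 6), unmasked = c(7, 8))
HARD_LEVELS <- list(masked = c(1, 2), unmasked = c(1, 2))

#' Refit an observer on a data subset
#'
#' Three subset analyses: `incorrect_only` restricts the likelihood product
#' to the two orientation-incorrect outcomes (scores only — probing how
#' well a model predicts Type-2 false alarms); `easy` and `hard` restrict
#' the data to the two easiest / two hardest levels (masked: ISI 83.3 and
#' 100 ms vs 16.7 and 33.3 ms; unmasked: 2557 and 3000 us vs 980 and
#' 1150 us) and refit evidence strengths and sigma_D on that subset, so
#' easy-vs-hard sigma estimates can be compared. For the easy subset,
#' participants below 70% orientation accuracy in those levels are
#' rejected; for the hard subset, participants at or above 70%.
#'
#' @param trials One participant's `trial_records` for one task.
#' @param spec An [observer_spec()].
#' @param subset `"incorrect_only"`, `"easy"` or `"hard"`.
#' @param variant `"ideal"` or `"noisy"`.
#' @param table Optional precomputed `prediction_table`.
#' @param n_sim,seed Table simulation settings when `table` is `NULL`.
#' @return For `incorrect_only`: list with `logL`, `sigma_d_hat`, `bic`,
#'   `k`, `n_total`. For `easy`/`hard`: an `observer_fit` restricted to the
#'   two levels.
#' @export
fit_subset <- function(trials, spec,
                       subset = c("incorrect_only", "easy", "hard"),
                       variant = c("noisy", "ideal"), table = NULL,
                       n_sim = 1e4, seed = 1) {
  subset <- match.arg(subset)
  variant <- match.arg(variant)
  tk <- single_task(trials)
  if (is.null(table)) {
    table <- simulate_prediction_table(spec, n_sim = n_sim, seed = seed)
  }
  if (subset == "incorrect_only") {
    if (all(trials$ori_correct)) {
      stop("empty subset: no incorrect-orientation trials", call. = FALSE)
    }
    level_indices <- sort(unique(trials$level_index))
    counts <- trial_counts_by_level(trials, level_indices)
    xs <- scale_levels(condition_levels(tk)$physical_value)
    acc <- parametric_percent_correct(counts$n11 + counts$n10, counts$n,
                                      xs[level_indices])
    c_hat <- fit_evidence_strengths(table, round(counts$n * acc), counts$n)
    counts_inc <- counts
    counts_inc$n11 <- 0; counts_inc$n10 <- 0
    counts_inc$n <- counts_inc$n01 + counts_inc$n00
    if (variant == "ideal") {
      s_hat <- 0
      logL <- joint_log_likelihood(table, c_hat, 0, counts_inc)
      k_par <- length(c_hat)
    } else {
      sf <- fit_sigma_d(table, c_hat, counts_inc)
      s_hat <- sf$sigma_d_hat; logL <- sf$logL
      k_par <- length(c_hat) + 1
    }
    n_total <- sum(counts_inc$n)
    return(list(logL = logL, sigma_d_hat = s_hat,
                bic = bic(logL, k_par, n_total), k = k_par,
                n_total = n_total, c_hat = c_hat))
  }
  levels_keep <- if (subset == "easy") EASY_LEVELS[[tk]] else HARD_LEVELS[[tk]]
  sub <- trials[trials$level_index %in% levels_keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty subset: no trials at those levels",
                            call. = FALSE)
  acc_sub <- mean(sub$ori_correct)
  if (subset == "easy" && acc_sub < 0.70) {
    stop("participant below 70% accuracy in the easy levels; excluded",
         call. = FALSE)
  }
  if (subset == "hard" && acc_sub >= 0.70) {
    stop("participant at or above 70% accuracy in the hard levels; excluded",
         call. = FALSE)
  }
  class(sub) <- c("trial_records", "data.frame")
  fit_observer(sub, spec, variant = variant, table = table, seed = seed,
               cv = FALSE)
}
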