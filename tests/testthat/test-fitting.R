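# Observer fitting: percent-correct preprocessing, monotone-constrained
# evidence strengths, likelihoods, BIC, cross-validation, subsets.

make_table <- function(model_id = 1, c_values = seq(0, 2, by = 0.2),
                       sigma_values = c(0, 0.25, 0.5, 0.75, 1),
                       n_sim = 1e4, seed = 77) {
  simulate_prediction_table(observer_spec(model_id), c_values = c_values,
                            sigma_values = sigma_values, n_sim = n_sim,
                            seed = seed)
}

# Brute-force constrained optimum: enumerate every monotone level-to-grid
# assignment. Independent of the dynamic-programming path.
enumerate_best_c <- function(table, k, n) {
  p <- pmin(pmax(pt_ori_correct(table), 1e-6), 1 - 1e-6)
  G <- length(p); L <- length(k)
  combos <- as.matrix(expand.grid(rep(list(seq_len(G)), L)))
  combos <- combos[apply(combos, 1, function(r) all(diff(r) >= 0)), ,
                   drop = FALSE]
  score <- apply(combos, 1, function(r) {
    sum(k * log(p[r]) + (n - k) * log(1 - p[r]))
  })
  table$c_values[combos[which.max(score), ]]
}

test_that("parametric percent correct is monotone, floored and faithful", {
  x <- scale_levels(condition_levels("masked")$physical_value)
  n <- rep(137, 6)
  raw_acc <- seq(0.55, 0.95, length.out = 6)
  k <- withr::with_seed(201, rbinom(6, n, raw_acc))
  fitted <- parametric_percent_correct(k, n, x)
  expect_true(all(diff(fitted) >= 0))
  expect_true(all(abs(fitted - raw_acc) < 0.05))
  # below-chance raw accuracy is floored at 0.5
  k2 <- round(n * c(0.45, 0.5, 0.6, 0.7, 0.8, 0.9))
  expect_gte(parametric_percent_correct(k2, n, x)[1], 0.5)
  # flat chance data fit to ~0.5 everywhere
  expect_equal(parametric_percent_correct(rep(68, 6), n, x), rep(0.5, 6),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("constrained evidence-strength fit equals exhaustive enumeration", {
  tab <- make_table(c_values = seq(0, 2, by = 0.2))  # 11-point grid
  n <- rep(137, 3)
  targets <- list(c(70, 90, 120), c(90, 80, 100), c(69, 69, 69),
                  c(120, 90, 70))  # includes non-monotone raw targets
  for (k in targets) {
    dp <- fit_evidence_strengths(tab, k, n)
    expect_equal(dp, enumerate_best_c(tab, k, n))
    expect_true(all(diff(dp) >= 0))
  }
})

test_that("chance-level targets map to zero evidence strength", {
  tab <- make_table(c_values = seq(0, 2, by = 0.1), n_sim = 2e4)
  n <- rep(137, 4)
  c_hat <- fit_evidence_strengths(tab, round(n / 2), n)
  expect_equal(c_hat, rep(0, 4))
})

test_that("evidence strengths are recovered from model-generated counts", {
  spec <- observer_spec(1)
  tab <- simulate_prediction_table(spec, n_sim = 2e4, seed = 78)
  true_c <- c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0)
  p_true <- pt_ori_correct(tab)[match(true_c, tab$c_values)]
  # expected counts at 137 trials/level: the estimator is calibrated
  k <- round(137 * p_true)
  c_hat <- fit_evidence_strengths(tab, k, rep(137, 6))
  expect_true(all(abs(c_hat - true_c) <= 0.2))
  # with binomial sampling noise the aggregate error stays small even
  # though ceiling levels are weakly identified
  k2 <- withr::with_seed(202, rbinom(6, 137, p_true))
  c_hat2 <- fit_evidence_strengths(tab, k2, rep(137, 6))
  expect_lte(sqrt(mean((c_hat2 - true_c)^2)), 0.3)
})

test_that("joint log-likelihood matches hand and trial-level computation", {
  tab <- make_table()
  # single level, all mass in one cell
  counts <- data.frame(n11 = 10, n10 = 0, n01 = 0, n00 = 0)
  p <- pt_cell(tab, 1, 0)
  expect_equal(joint_log_likelihood(tab, 1, 0, counts), 10 * log(p["p11"]),
               ignore_attr = TRUE)
  # equals the brute-force trial-by-trial sum
  counts2 <- data.frame(n11 = c(5, 9), n10 = c(3, 2), n01 = c(2, 4),
                        n00 = c(6, 1))
  c_hat <- c(0.4, 1.2)
  by_trial <- 0
  for (l in 1:2) {
    pl <- pmax(pt_cell(tab, c_hat[l], 0.25), 1e-6)
    cell_counts <- as.numeric(counts2[l, ])
    for (j in 1:4) by_trial <- by_trial + cell_counts[j] * unname(log(pl[j]))
  }
  expect_equal(joint_log_likelihood(tab, c_hat, 0.25, counts2), by_trial)
  # invariant to permuting level order
  expect_equal(joint_log_likelihood(tab, rev(c_hat), 0.25, counts2[2:1, ]),
               joint_log_likelihood(tab, c_hat, 0.25, counts2))
  expect_error(joint_log_likelihood(tab, c_hat, 0.25, counts2[1, ]),
               "different numbers of levels")
})

test_that("BIC follows the definition and its identities", {
  expect_equal(bic(-100, 6, 822), 200 + 6 * log(822))
  expect_equal(bic(-100, 0, 822), 200)
  expect_error(bic(-100, 6, 0), "positive")
  # same logL, one extra parameter: difference is exactly log(n)
  expect_equal(bic(-50, 7, 822) - bic(-50, 6, 822), log(822))
  logL_i <- -120; logL_n <- -115
  expect_equal(bic(logL_i, 6, 500) - bic(logL_n, 7, 500),
               2 * (logL_n - logL_i) - log(500))
})

test_that("sigma_D grid fit dominates sigma = 0 and recovers truth", {
  spec <- observer_spec(1)
  tab <- simulate_prediction_table(spec, c_values = seq(0, 3, by = 0.1),
                                   sigma_values = seq(0, 1, by = 0.05),
                                   n_sim = 2e4, seed = 79)
  true_c <- c(0.6, 1.2, 1.8, 2.4)
  gen <- function(sigma) {
    do.call(rbind, lapply(seq_along(true_c), function(l) {
      pr <- pt_cell(tab, true_c[l], sigma)
      as.data.frame(t(stats::rmultinom(1, 1000, pr)))
    }))
  }
  for (true_s in c(0, 0.5)) {
    counts <- withr::with_seed(203 + round(10 * true_s), {
      out <- gen(true_s)
      names(out) <- c("n11", "n10", "n01", "n00")
      out
    })
    fit <- fit_sigma_d(tab, true_c, counts)
    expect_gte(fit$logL, joint_log_likelihood(tab, true_c, 0, counts))
    expect_lte(abs(fit$sigma_d_hat - true_s), 0.15)
  }
})

test_that("fold assignment balances per-level counts within one trial", {
  lev <- rep(1:6, times = c(137, 137, 128, 144, 137, 137))
  fold <- withr::with_seed(204, vernier2ifc:::assign_folds(lev, 10))
  for (li in 1:6) {
    tab <- table(fold[lev == li])
    expect_lte(max(tab) - min(tab), 1)
    expect_length(tab, 10)
  }
})

test_that("ideal-observer CV score equals the full-data log-likelihood", {
  tr <- small_trials(seed = 205, n_participants = 1, trials = 60,
                     model_id = 1)
  spec <- observer_spec(1)
  tab <- simulate_prediction_table(spec, c_values = seq(0, 3, by = 0.1),
                                   sigma_values = seq(0, 1, by = 0.1),
                                   n_sim = 5e3, seed = 80)
  fit <- fit_observer(tr, spec, "ideal", table = tab, seed = 3,
                      resamples = 2)
  expect_equal(fit$cv$mean, fit$logL)
  expect_equal(fit$cv$sem, 0)
})

test_that("noisy-observer CV is seed-deterministic and finite", {
  tr <- small_trials(seed = 206, n_participants = 1, trials = 60,
                     model_id = 1, sigma_d = 0.4)
  spec <- observer_spec(1)
  tab <- simulate_prediction_table(spec, c_values = seq(0, 3, by = 0.1),
                                   sigma_values = seq(0, 1, by = 0.1),
                                   n_sim = 5e3, seed = 81)
  f1 <- fit_observer(tr, spec, "noisy", table = tab, seed = 4,
                     resamples = 3)
  f2 <- fit_observer(tr, spec, "noisy", table = tab, seed = 4,
                     resamples = 3)
  expect_identical(f1$cv$scores, f2$cv$scores)
  expect_true(all(is.finite(f1$cv$scores)))
  expect_equal(f1$k, length(f1$c_hat) + 1)
  expect_true(all(diff(f1$c_hat) >= 0))
  # the printed combination log(mean L_i) never exceeds the mean-log variant
  alt <- cv_logl(tab, f1$c_hat, tr, "noisy", folds = 10, resamples = 3,
                 seed = 4, combine = "mean_log")
  expect_true(all(f1$cv$scores >= alt$scores))
})

test_that("subset refits enforce their screens and restrictions", {
  spec <- observer_spec(1)
  tab <- simulate_prediction_table(spec, c_values = seq(0, 3, by = 0.1),
                                   sigma_values = seq(0, 1, by = 0.1),
                                   n_sim = 5e3, seed = 82)
  # a perfect discriminator leaves nothing for the incorrect-only refit
  perfect <- small_trials(seed = 207, n_participants = 1, trials = 20)
  perfect$resp_orientation_op <- perfect$offset_orientation
  perfect <- vernier2ifc:::validate_trials(as.data.frame(perfect))
  expect_error(fit_subset(perfect, spec, "incorrect_only", table = tab),
               "empty subset")

  # weak performer everywhere: rejected by the easy-level 70% screen
  weak <- generate_dataset(ground_truth("masked", model_id = 1,
                                        n_participants = 1,
                                        c_levels = rep(0.1, 6),
                                        participant_spread = 0,
                                        trials_per_level = 80),
                           seed = 208)
  expect_error(fit_subset(weak, spec, "easy", table = tab), "70%")
  # ... and accepted by the hard screen, restricted to the two hardest levels
  hard_fit <- fit_subset(weak, spec, "hard", table = tab)
  expect_equal(hard_fit$level_indices, c(1, 2))
  expect_length(hard_fit$c_hat, 2)

  # strong performer: easy subset fits, hard screen rejects
  strong <- generate_dataset(ground_truth("masked", model_id = 1,
                                          n_participants = 1,
                                          c_levels = rep(2.5, 6),
                                          participant_spread = 0,
                                          trials_per_level = 80),
                             seed = 209)
  easy_fit <- fit_subset(strong, spec, "easy", table = tab)
  expect_equal(easy_fit$level_indices, c(5, 6))
  expect_error(fit_subset(strong, spec, "hard", table = tab), "70%")

  # incorrect-only scores exist for an imperfect observer
  mid <- small_trials(seed = 210, n_participants = 1, trials = 60,
                      model_id = 1, sigma_d = 0.3)
  inc <- fit_subset(mid, spec, "incorrect_only", table = tab)
  expect_true(is.finite(inc$logL))
  expect_equal(inc$n_total, sum(!mid$ori_correct))
})
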