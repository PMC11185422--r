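# The seven 2D-SDT observers: evidence geometry, decisions, noise,
# prediction tables.

test_that("source means follow the evidence-space geometry", {
  expect_equal(source_mean("origin", "left", 2), c(2, 0))
  expect_equal(source_mean("origin", "right", 2), c(0, 2))
  expect_equal(source_mean("diagonal", "neutral", 2), c(1, 1))
  expect_equal(source_mean("origin", "neutral", 2), c(0, 0))
  expect_equal(source_mean("diagonal", "absent", 3), c(0, 0))
  for (kind in c("left", "right", "neutral", "absent")) {
    expect_equal(source_mean("origin", kind, 0), c(0, 0))
  }
  expect_error(source_mean("origin", "left", -1), "nonnegative")
})

test_that("evidence samples have the stated means and identity covariance", {
  spec <- observer_spec(3)
  sims <- withr::with_seed(101, {
    replicate(2e4, unlist(sample_evidence(spec, 3, "left")))
  })
  m <- rowMeans(sims)
  expect_equal(unname(m[c("d_op1", "d_op2")]), c(3, 0), tolerance = 0.02)
  expect_equal(unname(m[c("d_oa1", "d_oa2")]), c(1.5, 1.5), tolerance = 0.02)
  cv <- cov(t(sims[c("d_op1", "d_op2"), ]))
  expect_equal(unname(cv), diag(2), tolerance = 0.03)
  # c = 0: everything collapses onto the standard normal at the origin
  sims0 <- withr::with_seed(102, {
    replicate(2e4, unlist(sample_evidence(spec, 0, "right")))
  })
  expect_equal(unname(rowMeans(sims0)), rep(0, 4), tolerance = 0.03)
})

test_that("orientation posteriors match the brute-force density oracle", {
  grid <- seq(0, 5, by = 0.1)
  ds <- withr::with_seed(103, {
    lapply(1:120, function(i) rnorm(2, sd = 2))
  })
  for (d in ds) {
    pm <- orientation_decision(observer_spec(1), d)$p_left
    expect_equal(pm, oracle_p_left_marg(d, grid), tolerance = 1e-10)
    ph <- orientation_decision(observer_spec(2), d)$p_left
    expect_equal(ph, oracle_p_left_hier(d, grid), tolerance = 1e-10)
  }
})

test_that("orientation choice is dominance-driven with fair tie-breaks", {
  spec <- observer_spec(1)
  dec <- orientation_decision(spec, c(3, 0))
  expect_equal(dec$s_chosen, "left")
  expect_gt(dec$posterior, 0.5)
  # a sample on the main diagonal is perfectly ambiguous
  dec_tie <- orientation_decision(spec, c(1.3, 1.3))
  expect_equal(dec_tie$posterior, 0.5, tolerance = 1e-12)
  choices <- withr::with_seed(104, {
    vapply(1:400, function(i)
      orientation_decision(spec, c(1.3, 1.3))$s_chosen, character(1))
  })
  expect_gt(mean(choices == "left"), 0.4)
  expect_lt(mean(choices == "left"), 0.6)
  # hierarchical models expose the estimated strength
  expect_true(!is.null(orientation_decision(observer_spec(2), c(2, 0))$c_hat))
  expect_null(orientation_decision(observer_spec(1), c(2, 0))$c_hat)
})

test_that("interval decision variable is antisymmetric with OA on ties", {
  for (m in 1:7) {
    spec <- observer_spec(m)
    d1 <- c(1.7, 0.4); d2 <- c(0.2, 0.9)
    out <- withr::with_seed(105, interval_decision(spec, d1, d2))
    swapped <- withr::with_seed(105, interval_decision(spec, d2, d1))
    expect_equal(out$D, -swapped$D, tolerance = 1e-12)
    # identical samples: D = 0, the offset-absent interval is selected
    tied <- interval_decision(spec, d1, d1)
    expect_equal(tied$D, 0)
    expect_equal(tied$interval_choice, "OA")
  }
})

test_that("model-1 decision variable matches a hand computation", {
  # single-strength grid makes the posteriors closed-form
  spec <- observer_spec(1, c_grid = 2)
  d_op <- c(2, 0); d_oa <- c(0, 0)
  post <- function(d) {
    l <- dnorm(d[1], 2, 1) * dnorm(d[2], 0, 1)
    r <- dnorm(d[1], 0, 1) * dnorm(d[2], 2, 1)
    max(l, r) / (l + r)
  }
  out <- interval_decision(spec, d_op, d_oa)
  expect_equal(out$D, log(post(d_op) / post(d_oa)), tolerance = 1e-10)
  expect_equal(out$interval_choice, "OP")
})

test_that("noise injection degrades only the interval judgment", {
  expect_identical(inject_noise(1.23, 0), 1.23)
  expect_error(inject_noise(1, -0.1), "nonnegative")
  spec <- observer_spec(1)
  tab <- simulate_prediction_table(spec, c_values = c(0, 1, 2),
                                   sigma_values = c(0, 0.5, 5, 50),
                                   n_sim = 2e4, seed = 9)
  # orientation marginal sigma-invariant (common random numbers): the
  # stored marginal is a single count, and the cell sums agree to rounding
  ori <- tab$p["p11", , ] + tab$p["p10", , ]
  for (s in 2:4) {
    expect_equal(ori[, 1], ori[, s], tolerance = 1e-12)
    expect_equal(ori[, s], pt_ori_correct(tab), tolerance = 1e-12)
  }
  # overwhelming noise pushes interval accuracy to chance at every c
  int_acc <- tab$p["p11", , 4] + tab$p["p01", , 4]
  expect_equal(unname(int_acc), rep(0.5, 3), tolerance = 0.015)
})

test_that("prediction tables are proper joint distributions", {
  for (m in c(1, 2, 5, 7)) {
    tab <- simulate_prediction_table(observer_spec(m),
                                     c_values = c(0, 0.8, 2.5),
                                     sigma_values = c(0, 0.3),
                                     n_sim = 5e3, seed = 10 + m)
    sums <- apply(tab$p, c(2, 3), sum)
    expect_equal(unname(sums), matrix(1, 3, 2), tolerance = 1e-12)
    expect_true(all(tab$p >= 0))
    # orientation accuracy rises with evidence strength
    expect_true(all(diff(pt_ori_correct(tab)) > -0.01))
  }
})

test_that("marginalizing observers are at chance on all counts at c = 0", {
  # at zero signal the four joint outcomes are independent fair coins for
  # the marginalizing observers (ties in D are measure-zero there)
  for (m in c(1, 3, 5, 6)) {
    tab <- simulate_prediction_table(observer_spec(m), c_values = 0,
                                     sigma_values = 0, n_sim = 4e4,
                                     seed = 20 + m)
    expect_equal(unname(tab$p[, 1, 1]), rep(0.25, 4), tolerance = 0.015)
  }
})

test_that("hierarchical observers choose OA on their decision-tie atom", {
  # the discrete c-hat estimate can make both intervals' posteriors exactly
  # equal at weak signal; the tie rule then forces the OA interval, so
  # interval accuracy sits below chance at c = 0 while orientation accuracy
  # stays at 1/2 -- a structural property of these observers
  for (m in c(2, 4)) {
    tab <- simulate_prediction_table(observer_spec(m), c_values = 0,
                                     sigma_values = 0, n_sim = 4e4,
                                     seed = 30 + m)
    ori <- tab$p["p11", 1, 1] + tab$p["p10", 1, 1]
    int <- tab$p["p11", 1, 1] + tab$p["p01", 1, 1]
    expect_equal(unname(ori), 0.5, tolerance = 0.01)
    expect_lt(unname(int), 0.49)
  }
})

test_that("model 5 is strategy-invariant", {
  s_marg <- observer_spec(5, strategy = "marginalize")
  s_hier <- observer_spec(5, strategy = "hierarchical")
  t1 <- simulate_prediction_table(s_marg, c_values = c(0, 1, 2),
                                  sigma_values = c(0, 1), n_sim = 5e3,
                                  seed = 55)
  t2 <- simulate_prediction_table(s_hier, c_values = c(0, 1, 2),
                                  sigma_values = c(0, 1), n_sim = 5e3,
                                  seed = 55)
  expect_identical(t1$p, t2$p)
})

test_that("decisions are mirror-symmetric under left/right relabeling", {
  ds <- withr::with_seed(106, lapply(1:40, function(i) rnorm(2, sd = 1.5)))
  for (m in 1:7) {
    spec <- observer_spec(m)
    for (d in ds) {
      a <- orientation_decision(spec, d)
      b <- orientation_decision(spec, rev(d))
      expect_equal(a$p_left, 1 - b$p_left, tolerance = 1e-12)
    }
    # mirroring both intervals' samples leaves D unchanged
    d_op <- ds[[1]]; d_oa <- ds[[2]]
    D1 <- withr::with_seed(107, interval_decision(spec, d_op, d_oa))$D
    D2 <- withr::with_seed(107,
      interval_decision(spec, rev(d_op), rev(d_oa)))$D
    expect_equal(D1, D2, tolerance = 1e-12)
  }
})

test_that("interval accuracy is nonincreasing in sigma_D at fixed c", {
  for (m in c(1, 6)) {
    sig <- if (m == 1) c(0, 0.2, 0.5, 1) else c(0, 1, 3, 10)
    tab <- simulate_prediction_table(observer_spec(m), c_values = 1.5,
                                     sigma_values = sig, n_sim = 2e4,
                                     seed = 60 + m)
    int_acc <- tab$p["p11", 1, ] + tab$p["p01", 1, ]
    expect_true(all(diff(int_acc) <= 0.005))
  }
})

test_that("prediction tables serialize to the columnar layout", {
  tab <- simulate_prediction_table(observer_spec(3), c_values = c(0, 1),
                                   sigma_values = c(0, 0.1), n_sim = 1e3,
                                   seed = 70)
  df <- prediction_table_df(tab)
  expect_equal(nrow(df), 4)
  expect_named(df, c("model_id", "c", "sigma_d", "p11", "p10", "p01",
                     "p00", "n_sim", "seed"))
  expect_equal(df$p11 + df$p10 + df$p01 + df$p00, rep(1, 4))
  i <- which(df$c == 1 & df$sigma_d == 0.1)
  expect_equal(unname(pt_cell(tab, 1, 0.1)),
               unlist(df[i, c("p11", "p10", "p01", "p00")], use.names = FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_prediction_table(tab, path)
  expect_equal(nrow(utils::read.csv(path)), 4)
})
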